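# Genotype, panel and cross-design ingestion.
#
# The canonical in-memory container is the S3 class "geno_matrix":
#   $calls      character matrix, samples x markers, entries in
#               {"HOM1","HOM2","HET"} or NA for missing
#   $sample_ids rownames of $calls
#   $panel      data.frame of marker definitions (one row per column of $calls)
# Heterozygotes are unordered: "T:C" and "C:T" normalise to the same state.

#' Read a marker panel definition
#'
#' A panel file is a CSV with columns `marker_id`, `chromosome`, `pos_start`,
#' `pos_end`, `allele1`, `allele2`. Positions are 1-based inclusive genomic
#' coordinates as assayed; no liftover is attempted.
#'
#' @param path Path to a panel CSV.
#' @return A data.frame of class `marker_panel`, one row per marker, in file
#'   order.
#' @details Duplicate marker IDs and identical alleles are errors. A row whose
#'   `pos_start` exceeds `pos_end` triggers a warning only: the packaged QC
#'   panel reproduces its source table verbatim, including one row whose
#'   printed interval is inverted.
#' @export
read_marker_panel <- function(path) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("marker_id", "chromosome", "pos_start", "pos_end", "allele1", "allele2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("panel file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  df$chromosome <- as.integer(df$chromosome)
  df$pos_start <- as.numeric(df$pos_start)
  df$pos_end <- as.numeric(df$pos_end)
  validate_marker_panel(df)
}

#' Validate a marker panel data.frame
#'
#' @param df Data.frame with the panel columns (see [read_marker_panel()]).
#' @return The validated panel with class `marker_panel`.
#' @export
validate_marker_panel <- function(df) {
  if (anyDuplicated(df$marker_id)) {
    stop("duplicate marker_id in panel: ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  }
  bad <- df$allele1 == df$allele2
  if (any(bad)) {
    stop("allele1 == allele2 for marker(s): ",
         paste(df$marker_id[bad], collapse = ", "))
  }
  if (!all(nchar(df$allele1) == 1L & nchar(df$allele2) == 1L)) {
    stop("alleles must be single nucleotide characters")
  }
  inverted <- df$pos_start > df$pos_end
  if (any(inverted)) {
    warning("pos_start > pos_end for marker(s): ",
            paste(df$marker_id[inverted], collapse = ", "),
            " (kept as printed in the source panel)")
  }
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' Construct a genotype matrix
#'
#' @param calls Character matrix of call states (`"HOM1"`, `"HOM2"`, `"HET"`,
#'   `NA`), samples in rows, markers in columns. Rownames are sample IDs and
#'   colnames must equal `panel$marker_id`.
#' @param panel A `marker_panel`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, panel) {
  stopifnot(is.matrix(calls), !is.null(colnames(calls)))
  if (is.null(rownames(calls))) {
    if (nrow(calls) > 0) stop("calls must have sample IDs as rownames")
    rownames(calls) <- character(0)
  }
  if (anyDuplicated(rownames(calls))) {
    stop("duplicate sample IDs: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  }
  if (!identical(colnames(calls), panel$marker_id)) {
    stop("calls columns must match panel marker_ids exactly and in order")
  }
  ok <- is.na(calls) | calls %in% .CALL_STATES
  if (!all(ok)) {
    stop("invalid call state(s): ", paste(unique(calls[!ok]), collapse = ", "))
  }
  structure(list(calls = calls, sample_ids = rownames(calls), panel = panel),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "markers\n")
  cat("  missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(x$calls))), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# Normalise one raw allele-pair token against a marker definition.
# Returns a state string or NA; signals an error for foreign alleles.
.normalise_call <- function(token, a1, a2, sample_id, marker_id) {
  token <- trimws(token)
  if (is.na(token) || token %in% .MISSING_TOKENS) {
    return(NA_character_)
  }
  if (grepl("[:/]", token)) {
    alleles <- strsplit(token, "[:/]")[[1]]
  } else {
    alleles <- strsplit(token, "")[[1]]
  }
  if (length(alleles) != 2L) {
    stop("malformed genotype '", token, "' for sample ", sample_id,
         " at marker ", marker_id)
  }
  known <- alleles %in% c(a1, a2)
  if (!all(known)) {
    stop("allele(s) ", paste(alleles[!known], collapse = ","),
         " not in panel alleles {", a1, ",", a2, "} for sample ",
         sample_id, " at marker ", marker_id)
  }
  n1 <- sum(alleles == a1)
  if (n1 == 2L) "HOM1" else if (n1 == 0L) "HOM2" else "HET"
}

#' Read a genotype call table
#'
#' Two dialects are supported. `"grid"` is the genotyping-lab export layout:
#' samples as rows, first column the sample ID, one column per marker (header
#' row of marker IDs), cells holding allele pairs separated by `:` or `/`
#' (e.g. `"T:C"`), with `?`, `-`, `NA` or an empty cell for missing calls.
#' `"hapmap"` is the HapMap text layout written by [write_hapmap()]: markers
#' as rows with the 11 standard leading columns, two-letter genotype cells
#' (`"TC"`), `"NN"` for missing.
#'
#' @param path Path to the genotype file.
#' @param panel A `marker_panel` the calls are validated against.
#' @param dialect `"grid"` (CSV/TSV, auto-detected separator) or `"hapmap"`.
#' @return A validated [geno_matrix()] with calls normalised to
#'   HOM1/HOM2/HET/missing; heterozygote allele order in the file is
#'   irrelevant.
#' @export
read_genotype_table <- function(path, panel, dialect = c("grid", "hapmap")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "grid") .read_grid(path, panel) else .read_hapmap(path, panel)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.read_grid <- function(path, panel) {
  sep <- .detect_sep(path)
  fields <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(fields)) != 1L) {
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(fields), collapse = ", "), " fields")
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  sample_ids <- df[[1L]]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  marker_cols <- names(df)[-1L]
  if (!setequal(marker_cols, panel$marker_id)) {
    stop("genotype columns do not match the panel; missing: ",
         paste(setdiff(panel$marker_id, marker_cols), collapse = ", "),
         "; unknown: ", paste(setdiff(marker_cols, panel$marker_id), collapse = ", "))
  }
  df <- df[, c(names(df)[1L], panel$marker_id)]
  calls <- matrix(NA_character_, nrow = length(sample_ids), ncol = nrow(panel),
                  dimnames = list(sample_ids, panel$marker_id))
  for (j in seq_len(nrow(panel))) {
    a1 <- panel$allele1[j]; a2 <- panel$allele2[j]
    raw <- df[[j + 1L]]
    calls[, j] <- vapply(seq_along(raw), function(i) {
      .normalise_call(raw[i], a1, a2, sample_ids[i], panel$marker_id[j])
    }, character(1))
  }
  geno_matrix(calls, panel)
}

# HapMap: one row per marker; 11 leading columns then one column per sample.
.HAPMAP_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                  "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

.read_hapmap <- function(path, panel) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  if (ncol(df) < 12L) stop("HapMap file must have 11 leading columns plus samples")
  sample_ids <- names(df)[-(1:11)]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  marker_ids <- df[[1L]]
  if (!setequal(marker_ids, panel$marker_id)) {
    stop("HapMap markers do not match the panel")
  }
  df <- df[match(panel$marker_id, marker_ids), ]
  calls <- matrix(NA_character_, nrow = length(sample_ids), ncol = nrow(panel),
                  dimnames = list(sample_ids, panel$marker_id))
  for (j in seq_len(nrow(panel))) {
    a1 <- panel$allele1[j]; a2 <- panel$allele2[j]
    raw <- as.character(df[j, -(1:11)])
    calls[, j] <- vapply(seq_along(raw), function(i) {
      .normalise_call(raw[i], a1, a2, sample_ids[i], panel$marker_id[j])
    }, character(1))
  }
  geno_matrix(calls, panel)
}

#' Write a genotype matrix in HapMap dialect
#'
#' Genotype cells are two-letter allele pairs (`"TC"`), missing is `"NN"`,
#' chromosome is the panel's integer label and position is `pos_start`. The
#' output round-trips through `read_genotype_table(dialect = "hapmap")` with
#' identical call states.
#'
#' @param gm A `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  panel <- gm$panel
  cells <- sapply(seq_len(nrow(panel)), function(j) {
    a1 <- panel$allele1[j]; a2 <- panel$allele2[j]
    st <- gm$calls[, j]
    out <- rep("NN", length(st))
    out[!is.na(st) & st == "HOM1"] <- paste0(a1, a1)
    out[!is.na(st) & st == "HOM2"] <- paste0(a2, a2)
    out[!is.na(st) & st == "HET"] <- paste0(a1, a2)
    out
  })
  # sapply over markers gives samples x markers; HapMap wants markers as rows
  cells <- matrix(cells, nrow = nrow(gm$calls))
  geno <- t(cells)
  lead <- data.frame(
    `rs#` = panel$marker_id,
    alleles = paste0(panel$allele1, "/", panel$allele2),
    chrom = panel$chromosome,
    pos = panel$pos_start,
    strand = "+", `assembly#` = "v1.1", center = "NA", protLSID = "NA",
    assayLSID = "NA", panelLSID = "NA", QCcode = "NA",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out <- cbind(lead, as.data.frame(geno, stringsAsFactors = FALSE))
  names(out) <- c(.HAPMAP_COLS, gm$sample_ids)
  write.table_utf8(out, path)
  invisible(path)
}

write.table_utf8 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cross-design table
#'
#' A cross design maps each cross to its female parent, male parent and the
#' putative F1 samples derived from it. Expected CSV columns: `cross_id`,
#' `female_id`, `male_id`, `f1_ids` (a `;`-delimited list, possibly empty)
#' and optionally `source_group` (e.g. the trial stage the female was
#' recycled from).
#'
#' @param path Path to the design CSV.
#' @param genotypes Optional `geno_matrix`; crosses referencing samples absent
#'   from it are retained but a warning names them.
#' @return An object of class `cross_design`: a list with `$crosses` (one row
#'   per cross) and `$f1_map` (one row per F1: `f1_id`, `cross_id`).
#' @export
read_cross_design <- function(path, genotypes = NULL) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("cross_id", "female_id", "male_id", "f1_ids")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("design file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"source_group" %in% names(df)) df$source_group <- NA_character_
  f1_lists <- strsplit(df$f1_ids, ";", fixed = TRUE)
  f1_lists <- lapply(f1_lists, function(x) trimws(x[nzchar(trimws(x))]))
  cross_design(
    crosses = data.frame(cross_id = df$cross_id, female_id = df$female_id,
                         male_id = df$male_id, source_group = df$source_group,
                         stringsAsFactors = FALSE),
    f1_lists = f1_lists, genotypes = genotypes
  )
}

#' Construct a cross design
#'
#' @param crosses Data.frame with columns `cross_id`, `female_id`, `male_id`
#'   and optionally `source_group`.
#' @param f1_lists List (one element per cross) of character vectors of F1
#'   sample IDs.
#' @param genotypes Optional `geno_matrix` for referential checks (warning
#'   only; crosses are retained).
#' @return A `cross_design` object.
#' @export
cross_design <- function(crosses, f1_lists, genotypes = NULL) {
  stopifnot(is.data.frame(crosses), length(f1_lists) == nrow(crosses))
  if (!"source_group" %in% names(crosses)) crosses$source_group <- NA_character_
  if (anyDuplicated(crosses$cross_id)) {
    stop("duplicate cross_id(s): ",
         paste(unique(crosses$cross_id[duplicated(crosses$cross_id)]), collapse = ", "))
  }
  if (any(crosses$female_id == crosses$male_id)) {
    stop("female_id == male_id for cross(es): ",
         paste(crosses$cross_id[crosses$female_id == crosses$male_id], collapse = ", "))
  }
  all_f1 <- as.character(unlist(f1_lists, use.names = FALSE))
  if (anyDuplicated(all_f1)) {
    stop("F1 ID(s) assigned to more than one cross: ",
         paste(unique(all_f1[duplicated(all_f1)]), collapse = ", "))
  }
  f1_map <- data.frame(
    f1_id = all_f1,
    cross_id = rep(crosses$cross_id, lengths(f1_lists)),
    stringsAsFactors = FALSE
  )
  if (!is.null(genotypes)) {
    referenced <- unique(c(crosses$female_id, crosses$male_id, all_f1))
    absent <- setdiff(referenced, genotypes$sample_ids)
    if (length(absent) > 0) {
      warning(length(absent), " sample(s) referenced by the design are absent ",
              "from the genotype table: ",
              paste(utils::head(absent, 10L), collapse = ", "),
              if (length(absent) > 10L) ", ..." else "")
    }
  }
  structure(list(crosses = crosses, f1_map = f1_map), class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("cross_design:", nrow(x$crosses), "crosses,", nrow(x$f1_map), "F1s,",
      length(unique(c(x$crosses$female_id, x$crosses$male_id))), "parents\n")
  invisible(x)
}

#' Parent and F1 sample IDs of a design
#'
#' @param design A `cross_design`.
#' @return List with `$parents` (unique female then male IDs) and `$f1s`.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  list(parents = unique(c(design$crosses$female_id, design$crosses$male_id)),
       f1s = design$f1_map$f1_id)
}

#' Subset a genotype matrix by sample
#'
#' @param gm A `geno_matrix`.
#' @param sample_ids IDs to keep, in the given order.
#' @return A `geno_matrix` restricted to those samples.
#' @export
subset_samples <- function(gm, sample_ids) {
  stopifnot(inherits(gm, "geno_matrix"))
  unknown <- setdiff(sample_ids, gm$sample_ids)
  if (length(unknown) > 0) {
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "))
  }
  geno_matrix(gm$calls[sample_ids, , drop = FALSE], gm$panel)
}

#' Combine two genotype matrices over the same panel
#'
#' @param a,b `geno_matrix` objects sharing one panel; sample sets disjoint.
#' @return A `geno_matrix` with the rows of `a` then `b`.
#' @export
bind_samples <- function(a, b) {
  stopifnot(inherits(a, "geno_matrix"), inherits(b, "geno_matrix"))
  if (!identical(a$panel$marker_id, b$panel$marker_id)) {
    stop("panels differ")
  }
  geno_matrix(rbind(a$calls, b$calls), a$panel)
}

#' Write a genotype matrix as a call grid
#'
#' Inverse of the `"grid"` dialect of [read_genotype_table()]: samples as
#' rows, allele-pair cells like `"T:C"`, missing as `"?"`.
#'
#' @param gm A `geno_matrix`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_genotype_grid <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  panel <- gm$panel
  cells <- sapply(seq_len(nrow(panel)), function(j) {
    a1 <- panel$allele1[j]; a2 <- panel$allele2[j]
    st <- gm$calls[, j]
    out <- rep("?", length(st))
    out[!is.na(st) & st == "HOM1"] <- paste0(a1, ":", a1)
    out[!is.na(st) & st == "HOM2"] <- paste0(a2, ":", a2)
    out[!is.na(st) & st == "HET"] <- paste0(a1, ":", a2)
    out
  })
  cells <- matrix(cells, nrow = nrow(gm$calls))
  df <- data.frame(sample_id = gm$sample_ids, cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("sample_id", panel$marker_id)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cross design CSV
#'
#' @param design A `cross_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cross_design <- function(design, path) {
  stopifnot(inherits(design, "cross_design"))
  f1 <- split(design$f1_map$f1_id, factor(design$f1_map$cross_id,
                                          levels = design$crosses$cross_id))
  df <- design$crosses
  df$f1_ids <- vapply(f1, paste, character(1), collapse = ";")
  df <- df[, c("cross_id", "female_id", "male_id", "f1_ids", "source_group")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
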