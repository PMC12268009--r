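# Readers and writers for every on-disk artifact the pipeline touches.
# All readers validate strictly and raise on invariant violations, naming
# the offending row/column; they never silently coerce.

VALID_SEX <- c("F", "M")
VALID_TIMEPOINTS <- c("baseline", "acute", "trained")
VALID_LAYERS <- c("methylation_beta", "transcript_log2", "protein_log", "protein_raw")
VALID_CONTEXTS <- c("promoter", "gene_body", "intergenic")

#' Validate a sample sheet
#'
#' A sample sheet describes the cohort design: one row per sample with
#' subject, sex, age and timepoint. Invariants: unique `sample_id`, sex
#' constant within subject, at most one sample per (subject, timepoint).
#'
#' @param sheet data.frame with columns `sample_id`, `subject_id`, `sex`
#'   (`"F"`/`"M"`), `age` (years), `timepoint`
#'   (`"baseline"`/`"acute"`/`"trained"`).
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "subject_id", "sex", "age", "timepoint")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stopf("duplicate sample_id: %s", paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  bad_sex <- setdiff(unique(sheet$sex), VALID_SEX)
  if (length(bad_sex)) stopf("unknown sex label(s): %s", paste(bad_sex, collapse = ", "))
  bad_tp <- setdiff(unique(sheet$timepoint), VALID_TIMEPOINTS)
  if (length(bad_tp)) stopf("unknown timepoint label(s): %s", paste(bad_tp, collapse = ", "))
  sex_per_subj <- tapply(sheet$sex, sheet$subject_id, function(s) length(unique(s)))
  if (any(sex_per_subj > 1))
    stopf("sex is not constant within subject(s): %s",
          paste(names(sex_per_subj)[sex_per_subj > 1], collapse = ", "))
  key <- paste(sheet$subject_id, sheet$timepoint)
  if (anyDuplicated(key))
    stopf("duplicated (subject, timepoint) pair(s): %s", paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.numeric(sheet$age) || any(!is.finite(sheet$age)))
    stopf("age must be finite numeric")
  invisible(sheet)
}

#' Read / write a sample sheet (CSV)
#' @param path file path.
#' @return `read_sample_sheet`: validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an omics matrix
#'
#' A features x samples numeric matrix for one omics layer. Missing values
#' (`NA`) are permitted only for protein layers, where label-free
#' quantification leaves low-abundance proteins unobserved.
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param layer one of `"methylation_beta"`, `"transcript_log2"`,
#'   `"protein_log"`, `"protein_raw"`.
#' @return an `omics_matrix` object.
#' @export
omics_matrix <- function(values, layer) {
  layer <- match.arg(layer, VALID_LAYERS)
  if (!is.matrix(values) || !is.numeric(values)) stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate feature_id: %s", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample_id: %s", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) && !startsWith(layer, "protein"))
    stopf("missing values are only permitted in protein layers, found NA in layer '%s' (first at %s)",
          layer, format_cell(values, which(is.na(values))[1]))
  if (layer == "methylation_beta") {
    bad <- which(values < 0 | values > 1)
    if (length(bad))
      stopf("beta value out of [0,1] at %s (value %g)", format_cell(values, bad[1]), values[bad[1]])
  }
  structure(list(values = values, layer = layer), class = "omics_matrix")
}

format_cell <- function(m, idx) {
  rc <- arrayInd(idx, dim(m))
  sprintf("row '%s', column '%s'", rownames(m)[rc[1]], colnames(m)[rc[2]])
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples, %d missing\n",
              x$layer, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read / write an omics matrix (TSV, features in rows)
#'
#' TSV with a header row of sample ids and a first column `feature_id`.
#' Empty cells and `"NA"` are read as missing; missing cells are written
#' empty.
#'
#' @param path file path.
#' @param layer layer label, see [omics_matrix()].
#' @return `read_omics_matrix`: an `omics_matrix`.
#' @export
read_omics_matrix <- function(path, layer) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (names(df)[1] != "feature_id") stopf("first column of %s must be 'feature_id'", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric cell(s) in matrix %s", path)
  rownames(m) <- ids
  omics_matrix(m, layer)
}

#' @rdname read_omics_matrix
#' @param mat an `omics_matrix`.
#' @export
write_omics_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "omics_matrix"))
  df <- data.frame(feature_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a CpG annotation table (TSV)
#'
#' Columns: `cpg_id`, `chrom`, `pos` (1-based, array-manifest convention),
#' `gene` (empty for intergenic), `context`
#' (`promoter`/`gene_body`/`intergenic`). A CpG is intergenic if and only
#' if its gene field is empty.
#'
#' @param path file path.
#' @return `read_cpg_annotation`: validated data.frame.
#' @export
read_cpg_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = character(0))
  validate_cpg_annotation(ann)
}

#' @rdname read_cpg_annotation
#' @param ann CpG annotation data.frame.
#' @export
write_cpg_annotation <- function(ann, path) {
  validate_cpg_annotation(ann)
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cpg_annotation
#' @export
validate_cpg_annotation <- function(ann) {
  req <- c("cpg_id", "chrom", "pos", "gene", "context")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stopf("CpG annotation missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$cpg_id))
    stopf("duplicate cpg_id: %s", paste(unique(ann$cpg_id[duplicated(ann$cpg_id)]), collapse = ", "))
  if (any(ann$pos < 1)) stopf("pos must be >= 1 (cpg %s)", ann$cpg_id[which(ann$pos < 1)[1]])
  bad_ctx <- setdiff(unique(ann$context), VALID_CONTEXTS)
  if (length(bad_ctx)) stopf("unknown context label(s): %s", paste(bad_ctx, collapse = ", "))
  ann$gene[is.na(ann$gene)] <- ""
  inter <- ann$context == "intergenic"
  if (any(inter != (ann$gene == ""))) {
    i <- which(inter != (ann$gene == ""))[1]
    stopf("context/gene mismatch for cpg %s: context '%s' but gene '%s'",
          ann$cpg_id[i], ann$context[i], ann$gene[i])
  }
  ann
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<tab>description<tab>member1<tab>member2...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line (need name, description, >=1 member): %s", l)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set name in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a fiber-type reference table (TSV)
#'
#' Percentage-abundance profiles of fiber-type-specific proteins across
#' slow type 1 and fast type 2a/2x fibers. Percentages must be
#' non-negative and sum to 100 (+/- 0.5) per protein.
#'
#' @param path file path.
#' @return data.frame with columns `protein_id`, `pct_type1`, `pct_type2a`,
#'   `pct_type2x`.
#' @export
read_fiber_reference <- function(path) {
  ref <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_fiber_reference(ref)
}

#' @rdname read_fiber_reference
#' @param ref fiber-type reference data.frame.
#' @export
write_fiber_reference <- function(ref, path) {
  validate_fiber_reference(ref)
  utils::write.table(ref, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_fiber_reference <- function(ref) {
  req <- c("protein_id", "pct_type1", "pct_type2a", "pct_type2x")
  miss <- setdiff(req, names(ref))
  if (length(miss)) stopf("fiber reference missing column(s): %s", paste(miss, collapse = ", "))
  p <- as.matrix(ref[, c("pct_type1", "pct_type2a", "pct_type2x")])
  if (any(p < 0)) stopf("negative percentage for protein %s", ref$protein_id[which(rowSums(p < 0) > 0)[1]])
  tot <- rowSums(p)
  bad <- which(abs(tot - 100) > 0.5)
  if (length(bad)) stopf("percentages for protein %s sum to %g, not 100", ref$protein_id[bad[1]], tot[bad[1]])
  ref
}

#' Write / read a JSON artifact (ground truth, summaries, reports)
#' @param x list to serialize.
#' @param path file path.
#' @export
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_artifact
#' @export
read_json_artifact <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
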