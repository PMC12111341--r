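#' Construct a labeled expression matrix
#'
#' Bundles a numeric genes x samples matrix with a per-sample class label
#' (`"tumor"` / `"normal"`).  This is the input container for REO pair
#' mining: only within-sample orderings are ever used downstream, so values
#' may be on any monotone scale (log intensities, normalized counts, ...).
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames), all values finite.
#' @param label character or factor of length `ncol(values)` with levels
#'   `"tumor"` and `"normal"`.
#' @return An object of class `labeled_expression`: a list with elements
#'   `values` and `label` (factor).
#' @export
labeled_expression <- function(values, label) {
  check_flag(is.matrix(values) && is.numeric(values), "input error: 'values' must be a numeric matrix")
  check_flag(all(is.finite(values)), "input error: expression values must be finite")
  check_flag(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
             "input error: duplicate or missing gene IDs")
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  check_flag(!anyDuplicated(colnames(values)), "input error: duplicate sample IDs")
  label <- as.character(label)
  check_flag(length(label) == ncol(values), "input error: one label per sample required")
  check_flag(all(label %in% c("tumor", "normal")),
             "input error: labels must be 'tumor' or 'normal'")
  new_tag(list(values = values, label = factor(label, levels = c("normal", "tumor"))),
          "labeled_expression")
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat(sprintf("labeled_expression: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$label == "tumor"), sum(x$label == "normal")))
  invisible(x)
}

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV layout: genes in rows, first column the gene ID, remaining columns
#' samples (header row holds sample IDs).  MTX layout: a triplet `.mtx` file
#' plus two sidecar files `<path>.rownames` and `<path>.colnames` with one
#' gene / sample ID per line.
#'
#' @param path file path (for `format = "mtx"`, the `.mtx` file).
#' @param format `"tsv"` or `"mtx"`.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_flag(file.exists(path), "input error: file '%s' does not exist", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    check_flag(ncol(dt) >= 2, "parse error in '%s': need gene column plus >=1 sample", path)
    genes <- as.character(dt[[1L]])
    dup <- genes[duplicated(genes)]
    check_flag(length(dup) == 0, "parse error in '%s': duplicate gene ID '%s'", path, dup[1L])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    check_flag(is.numeric(m), "parse error in '%s': non-numeric expression values", path)
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    check_flag(nrow(m) == length(rn) && ncol(m) == length(cn),
               "parse error in '%s': sidecar name files do not match matrix dimensions", path)
    dup <- rn[duplicated(rn)]
    check_flag(length(dup) == 0, "parse error in '%s': duplicate gene ID '%s'", path, dup[1L])
    dimnames(m) <- list(rn, cn)
  }
  m
}

#' Write an expression (or CNV) matrix as TSV or MatrixMarket
#'
#' Inverse of [read_expression()]; numeric values are written with fixed
#' 10-significant-digit formatting so output files are byte-stable.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (the latter writes `.rownames` /
#'   `.colnames` sidecars next to `path`).
#' @param id_col name of the gene-ID column in TSV output.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "mtx"), id_col = "gene") {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::data.table(gene = rownames(m))
    data.table::setnames(dt, "gene", id_col)
    for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- format_num(m[, j])
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes within a
#' set are dropped.
#'
#' @param path GMT file path.
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (named list of character vectors) and `source` (the path).
#' @export
read_gmt <- function(path) {
  check_flag(file.exists(path), "input error: file '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_input("parse error in '%s' line %d: GMT lines need name, description and >=1 gene",
                 path, i)
    sets[[fields[1L]]] <- unique(fields[-c(1L, 2L)])
  }
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character gene-ID vectors; no empty set allowed.
#' @param source free-text provenance string.
#' @return `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, source = "") {
  check_flag(is.list(sets) && length(sets) > 0 && !is.null(names(sets)) && all(nzchar(names(sets))),
             "input error: 'sets' must be a non-empty named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  check_flag(all(lengths(sets) > 0), "input error: empty gene set not allowed")
  new_tag(list(sets = sets, source = source), "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source, collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a survival table
#'
#' @param sample unique sample identifiers.
#' @param time positive event/censoring times (one unit throughout).
#' @param event 0 = censored, 1 = event.
#' @return `data.frame` of class `survival_table` with columns
#'   `sample`, `time`, `event`.
#' @export
survival_table <- function(sample, time, event) {
  sample <- as.character(sample)
  check_flag(!anyDuplicated(sample), "input error: duplicate sample IDs in survival table")
  check_flag(all(is.finite(time) & time > 0), "input error: survival times must be positive")
  check_flag(all(event %in% c(0, 1)), "input error: event indicator must be 0 or 1")
  check_flag(length(sample) == length(time) && length(time) == length(event),
             "input error: sample/time/event lengths differ")
  df <- data.frame(sample = sample, time = as.numeric(time), event = as.integer(event),
                   stringsAsFactors = FALSE)
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read / write a survival table as TSV
#' @param path TSV with columns sample, time, event.
#' @return [read_survival()] returns a `survival_table`.
#' @export
read_survival <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  check_flag(all(c("sample", "time", "event") %in% names(df)),
             "parse error in '%s': columns sample, time, event required", path)
  survival_table(df$sample, df$time, df$event)
}

#' @rdname read_survival
#' @param tab a `survival_table`.
#' @export
write_survival <- function(tab, path) {
  out <- data.frame(sample = tab$sample, time = format_num(tab$time), event = tab$event)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
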