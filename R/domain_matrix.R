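#' Parse protein domain annotations
#'
#' Reads tab-separated domain annotation output and returns one
#' annotation set per protein: the protein identifier together with the
#' set of InterPro accessions annotated to it. Two dialects are
#' supported and must be named explicitly (never sniffed):
#'
#' * `"interproscan"` — the standard InterProScan TSV: the protein
#'   accession is column 1 and the InterPro accession is column 12 when
#'   present (`"-"` or empty means no InterPro mapping for that match).
#'   Lines must have at least 11 columns.
#' * `"tsv2"` — a minimal `protein_id<TAB>domain_id` file; a line with
#'   an empty (or absent) second field records a protein with no
#'   domain.
#'
#' Accessions are deduplicated per protein (set semantics) and proteins
#' are returned in order of first appearance.
#'
#' @param input path to a file, or a character vector of lines.
#' @param dialect `"tsv2"` or `"interproscan"`.
#' @return A list of annotation sets, each a list with elements
#'   `protein_id` (string) and `domains` (character vector, possibly
#'   empty).
#' @export
#' @examples
#' lines <- c("P1\tIPR001304", "P1\tIPR000436", "P1\tIPR001304", "P2\t")
#' parse_annotations(lines, dialect = "tsv2")
parse_annotations <- function(input, dialect = c("tsv2", "interproscan")) {
  dialect <- match.arg(dialect)
  lines <- if (length(input) == 1L && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    as.character(input)
  }
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(list())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- character(length(lines))
  accs <- character(length(lines))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (dialect == "tsv2") {
      if (length(f) > 2L || length(f) < 1L || !nzchar(f[1L])) {
        stop("malformed annotation line ", i, ": expected 'protein_id<TAB>domain_id'",
             call. = FALSE)
      }
      ids[i] <- f[1L]
      accs[i] <- if (length(f) >= 2L) f[2L] else ""
    } else {
      if (length(f) < 11L || !nzchar(f[1L])) {
        stop("malformed annotation line ", i,
             ": InterProScan TSV requires >= 11 columns", call. = FALSE)
      }
      ids[i] <- f[1L]
      accs[i] <- if (length(f) >= 12L) f[12L] else ""
    }
  }
  accs[accs == "-"] <- ""

  uids <- unique(ids)
  out <- vector("list", length(uids))
  for (j in seq_along(uids)) {
    a <- accs[ids == uids[j]]
    a <- unique(a[nzchar(a)])
    out[[j]] <- list(protein_id = uids[j], domains = a)
  }
  out
}

#' Read a protein label file
#'
#' Reads a two-column `protein_id<TAB>class` file where class `1` marks
#' an antifreeze protein (positive sample) and `2` a non-AFP (negative
#' sample).
#'
#' @param path label file path.
#' @return Named integer vector of class codes (names are protein ids).
#' @export
read_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != 2L)
  if (length(bad)) {
    stop("malformed label line ", bad[1L], ": expected 'protein_id<TAB>class'",
         call. = FALSE)
  }
  ids <- vapply(fields, `[`, "", 1L)
  cls <- vapply(fields, `[`, "", 2L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in label file: ",
         ids[anyDuplicated(ids)], call. = FALSE)
  }
  if (!all(cls %in% c("1", "2"))) {
    stop("label class must be 1 (AFP) or 2 (non-AFP); found '",
         setdiff(cls, c("1", "2"))[1L], "'", call. = FALSE)
  }
  stats::setNames(as.integer(cls), ids)
}

#' Construct a DomainMatrix
#'
#' Low-level constructor; most users build matrices with
#' [build_domain_matrix()] or [generate_matrix()]. The incidence matrix
#' is stored sparse; labels use the coding 1 = AFP (positive),
#' 2 = non-AFP (negative).
#'
#' @param incidence binary matrix (dense or sparse) with protein row
#'   names and domain column names.
#' @param labels integer vector of class codes in `{1, 2}`, one per row.
#' @param removed integer vector `c(pos = , neg = )` counting proteins
#'   dropped for having no domain annotation.
#' @return An object of class `DomainMatrix`.
#' @export
domain_matrix <- function(incidence, labels, removed = c(pos = 0L, neg = 0L)) {
  incidence <- methods::as(methods::as(Matrix::Matrix(incidence, sparse = TRUE),
                                       "dMatrix"), "CsparseMatrix")
  labels <- as.integer(labels)
  if (length(labels) != nrow(incidence)) {
    stop("labels length (", length(labels), ") != number of rows (",
         nrow(incidence), ")", call. = FALSE)
  }
  if (length(labels) && !all(labels %in% c(1L, 2L))) {
    stop("labels must be 1 (AFP) or 2 (non-AFP)", call. = FALSE)
  }
  vals <- incidence@x
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("incidence values must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(rownames(incidence))) stop("duplicate row_ids", call. = FALSE)
  if (anyDuplicated(colnames(incidence))) stop("duplicate col_ids", call. = FALSE)
  structure(
    list(incidence = Matrix::drop0(incidence), labels = labels,
         removed = c(pos = as.integer(removed[["pos"]]),
                     neg = as.integer(removed[["neg"]]))),
    class = "DomainMatrix"
  )
}

#' @export
print.DomainMatrix <- function(x, ...) {
  cat("DomainMatrix: ", nrow(x$incidence), " proteins x ",
      ncol(x$incidence), " domains\n", sep = "")
  cat("  positives (AFP): ", sum(x$labels == 1L),
      " | negatives: ", sum(x$labels == 2L),
      " | density: ",
      if (length(x$incidence)) {
        signif(Matrix::nnzero(x$incidence) / length(x$incidence), 3)
      } else NA, "\n", sep = "")
  if (any(x$removed > 0L)) {
    cat("  removed (no domain annotation): ", x$removed[["pos"]],
        " positive, ", x$removed[["neg"]], " negative\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.DomainMatrix <- function(x) dim(x$incidence)

#' Build the binary protein-by-domain matrix
#'
#' Turns annotation sets plus a label map into the binary incidence
#' matrix used throughout the pipeline: entry (i, j) is 1 iff protein i
#' carries domain j. Proteins without any domain annotation are removed
#' (they carry no signal under this encoding) and counted per class;
#' proteins that appear in `labels` but not in `annotations` are
#' treated the same way. Row order is first appearance in
#' `annotations`; column order is first appearance of each accession.
#'
#' @param annotations list of annotation sets from [parse_annotations()].
#' @param labels named integer label map from [read_labels()] (1 = AFP,
#'   2 = non-AFP).
#' @return A [domain_matrix()] whose `removed` field counts dropped
#'   proteins per class.
#' @export
build_domain_matrix <- function(annotations, labels) {
  ids <- vapply(annotations, function(a) a$protein_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in annotations: ", ids[anyDuplicated(ids)],
         call. = FALSE)
  }
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab)) {
    stop("protein without label: ", paste(head(missing_lab, 5), collapse = ", "),
         call. = FALSE)
  }

  keep <- vapply(annotations, function(a) length(a$domains) > 0L, TRUE)
  removed_ids <- c(ids[!keep], setdiff(names(labels), ids))
  removed <- c(pos = sum(labels[removed_ids] == 1L),
               neg = sum(labels[removed_ids] == 2L))

  kept <- annotations[keep]
  row_ids <- ids[keep]
  col_ids <- unique(unlist(lapply(kept, `[[`, "domains"), use.names = FALSE))

  ns <- vapply(kept, function(a) length(a$domains), 0L)
  i <- rep.int(seq_along(kept), ns)
  j <- match(unlist(lapply(kept, `[[`, "domains"), use.names = FALSE), col_ids)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(row_ids), length(col_ids)),
                              dimnames = list(row_ids, col_ids))
  domain_matrix(inc, labels[row_ids], removed = removed)
}

#' Write a DomainMatrix to disk
#'
#' Two plain-text storage formats are supported:
#'
#' * `"triplet"` — a sparse triplet TSV with header lines `#rows`,
#'   `#cols` and `#labels` (tab-separated orders and labels) followed
#'   by one `row_id<TAB>col_id<TAB>1` line per incidence.
#' * `"mtx"` — MatrixMarket coordinate format with sidecar `.rows`,
#'   `.cols` and `.labels` text files next to the `.mtx` file.
#'
#' `write_domain_matrix()` followed by [read_domain_matrix()] is the
#' identity on (row ids, column ids, values, labels).
#'
#' @param matrix a `DomainMatrix`.
#' @param path output path (use an `.mtx` extension for MatrixMarket).
#' @param format `"auto"` (by extension), `"triplet"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_domain_matrix <- function(matrix, path, format = c("auto", "triplet", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "triplet"
  }
  inc <- matrix$incidence
  if (format == "triplet") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("#rows", rownames(inc)), collapse = "\t"), con)
    writeLines(paste(c("#cols", colnames(inc)), collapse = "\t"), con)
    writeLines(paste(c("#labels", matrix$labels), collapse = "\t"), con)
    tr <- methods::as(inc, "TsparseMatrix")
    if (length(tr@i)) {
      o <- order(tr@i, tr@j)
      writeLines(paste(rownames(inc)[tr@i[o] + 1L],
                       colnames(inc)[tr@j[o] + 1L], "1", sep = "\t"), con)
    }
  } else {
    Matrix::writeMM(inc, path)
    base <- sub("\\.mtx$", "", path)
    writeLines(rownames(inc) %||% character(), paste0(base, ".rows"))
    writeLines(colnames(inc) %||% character(), paste0(base, ".cols"))
    writeLines(as.character(matrix$labels), paste0(base, ".labels"))
  }
  invisible(path)
}

#' Read a DomainMatrix from disk
#'
#' @param path file written by [write_domain_matrix()].
#' @inheritParams write_domain_matrix
#' @return A `DomainMatrix`. Incidence values other than 0/1 or labels
#'   outside `{1, 2}` are rejected with a format error.
#' @export
read_domain_matrix <- function(path, format = c("auto", "triplet", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "triplet"
  }
  if (format == "triplet") {
    lines <- readLines(path, warn = FALSE)
    hdr <- function(tag) {
      ln <- lines[startsWith(lines, paste0("#", tag))]
      if (length(ln) != 1L) stop("format error: missing #", tag, " header", call. = FALSE)
      strsplit(ln, "\t", fixed = TRUE)[[1L]][-1L]
    }
    row_ids <- hdr("rows"); col_ids <- hdr("cols"); labels <- hdr("labels")
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(body)) {
      f <- strsplit(body, "\t", fixed = TRUE)
      if (any(vapply(f, length, 0L) != 3L)) {
        stop("format error: triplet lines must be row_id<TAB>col_id<TAB>value",
             call. = FALSE)
      }
      val <- vapply(f, `[`, "", 3L)
      if (!all(val == "1")) {
        stop("format error: incidence value must be 1, found '",
             setdiff(val, "1")[1L], "'", call. = FALSE)
      }
      i <- match(vapply(f, `[`, "", 1L), row_ids)
      j <- match(vapply(f, `[`, "", 2L), col_ids)
      if (anyNA(i) || anyNA(j)) {
        stop("format error: triplet references an id absent from headers",
             call. = FALSE)
      }
    } else {
      i <- integer(); j <- integer()
    }
    inc <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                                dims = c(length(row_ids), length(col_ids)),
                                dimnames = list(row_ids, col_ids))
  } else {
    inc <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    base <- sub("\\.mtx$", "", path)
    row_ids <- readLines(paste0(base, ".rows"), warn = FALSE)
    col_ids <- readLines(paste0(base, ".cols"), warn = FALSE)
    labels <- readLines(paste0(base, ".labels"), warn = FALSE)
    dimnames(inc) <- list(row_ids, col_ids)
  }
  if (!all(labels %in% c("1", "2"))) {
    stop("format error: labels must be 1 or 2", call. = FALSE)
  }
  domain_matrix(inc, as.integer(labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
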