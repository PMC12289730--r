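#' Read a labeled matrix from TSV
#'
#' Reads the package's canonical matrix dialect: UTF-8, tab-separated,
#' `.` decimal point, first row holds column identifiers preceded by an
#' empty cell, first column holds row identifiers, every remaining cell a
#' decimal number. Identifiers are kept in file order.
#'
#' @param path Path to a TSV matrix file.
#' @return A numeric matrix with `rownames`/`colnames` set from the file.
#' @seealso [write_matrix_tsv()] for the inverse operation.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("matrix file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 1L) {
    stop("empty matrix file: ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  n_col <- length(col_ids)
  body <- lines[-1L]
  row_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col)
  for (i in seq_along(body)) {
    cells <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != n_col + 1L) {
      stop(sprintf(
        "ragged row %d in %s: expected %d cells, found %d",
        i, path, n_col + 1L, length(cells)
      ), call. = FALSE)
    }
    row_ids[[i]] <- cells[[1L]]
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[[1L]]
      stop(sprintf(
        "non-numeric cell at row '%s', column '%s' in %s",
        cells[[1L]], col_ids[[bad]], path
      ), call. = FALSE)
    }
    values[i, ] <- vals
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row id in ", path, ": ",
         row_ids[duplicated(row_ids)][[1L]], call. = FALSE)
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate column id in ", path, ": ",
         col_ids[duplicated(col_ids)][[1L]], call. = FALSE)
  }
  if (length(values) && !all(is.finite(values))) {
    stop("non-finite value in ", path, call. = FALSE)
  }
  dimnames(values) <- list(row_ids, col_ids)
  values
}

#' Write a labeled matrix as TSV
#'
#' Emits the dialect read by [read_matrix_tsv()] at full double precision,
#' so a write/read round trip reproduces the matrix exactly.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) && nrow(m) > 0L) {
    stop("matrix has no row names", call. = FALSE)
  }
  if (is.null(colnames(m)) && ncol(m) > 0L) {
    stop("matrix has no column names", call. = FALSE)
  }
  header <- paste(c("", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[[i]],
            format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Assemble a drug-disease dataset bundle from matrix files
#'
#' Loads the binary association matrix plus any number of drug and disease
#' similarity matrices, reorders every similarity matrix to the association
#' matrix's identifier order, and validates the bundle: associations strictly
#' in \{0,1\}, similarities in \[0,1\] and indexed by exactly the association
#' matrix's drugs (resp. diseases).
#'
#' @param assoc_path Path to the binary drug (rows) x disease (columns)
#'   association matrix.
#' @param drug_sim_paths Named character vector of paths to square
#'   drug-similarity matrices.
#' @param disease_sim_paths Named character vector of paths to square
#'   disease-similarity matrices.
#' @return A `dda_bundle`: list with elements `association` (binary matrix),
#'   `drug_sims` and `disease_sims` (named lists of matrices).
#' @export
load_bundle <- function(assoc_path, drug_sim_paths, disease_sim_paths) {
  association <- read_matrix_tsv(assoc_path)
  drug_sims <- lapply(drug_sim_paths, read_matrix_tsv)
  disease_sims <- lapply(disease_sim_paths, read_matrix_tsv)
  new_bundle(association, drug_sims, disease_sims)
}

#' Construct and validate a dataset bundle from in-memory matrices
#'
#' @param association Binary drug x disease matrix with dimnames.
#' @param drug_sims Named list of square drug-similarity matrices.
#' @param disease_sims Named list of square disease-similarity matrices.
#' @return A validated `dda_bundle` with every similarity matrix reordered
#'   to the association matrix's identifier order.
#' @export
new_bundle <- function(association, drug_sims, disease_sims) {
  stopifnot(is.matrix(association))
  if (!all(association %in% c(0, 1))) {
    stop("association matrix must be strictly binary (0/1)", call. = FALSE)
  }
  drugs <- rownames(association)
  diseases <- colnames(association)
  if (is.null(drugs) || is.null(diseases)) {
    stop("association matrix must carry row and column identifiers",
         call. = FALSE)
  }
  align <- function(s, ids, label) {
    if (is.null(rownames(s)) || is.null(colnames(s))) {
      stop(label, " similarity matrix lacks identifiers", call. = FALSE)
    }
    missing_r <- setdiff(ids, rownames(s))
    missing_c <- setdiff(ids, colnames(s))
    if (length(missing_r) || length(missing_c)) {
      stop(label, " similarity matrix is missing ids: ",
           paste(union(missing_r, missing_c), collapse = ", "),
           call. = FALSE)
    }
    s <- s[ids, ids, drop = FALSE]
    if (any(s < -1e-12) || any(s > 1 + 1e-12)) {
      stop(label, " similarity values must lie in [0,1]", call. = FALSE)
    }
    pmin(pmax(s, 0), 1)
  }
  dnames <- names(drug_sims) %||% rep("drug", length(drug_sims))
  snames <- names(disease_sims) %||% rep("disease", length(disease_sims))
  drug_sims <- stats::setNames(
    lapply(seq_along(drug_sims), function(i) {
      align(drug_sims[[i]], drugs, dnames[[i]])
    }), names(drug_sims))
  disease_sims <- stats::setNames(
    lapply(seq_along(disease_sims), function(i) {
      align(disease_sims[[i]], diseases, snames[[i]])
    }), names(disease_sims))
  structure(
    list(association = association, drug_sims = drug_sims,
         disease_sims = disease_sims),
    class = "dda_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dda_bundle <- function(x, ...) {
  m <- nrow(x$association); n <- ncol(x$association)
  cat(sprintf(
    "dda_bundle: %d drugs x %d diseases, %d known associations (%.2f%%)\n",
    m, n, sum(x$association), 100 * mean(x$association)
  ))
  cat("  drug similarities:    ",
      paste(names(x$drug_sims), collapse = ", "), "\n")
  cat("  disease similarities: ",
      paste(names(x$disease_sims), collapse = ", "), "\n")
  invisible(x)
}

#' Write ranked candidate predictions
#'
#' Writes a TSV of the top-scoring unknown drug-disease pairs per drug:
#' columns `drug_id`, `disease_id`, `score`, `rank`. Pairs already positive
#' in the training matrix are excluded; within a drug, candidates sort by
#' score descending with ties broken by disease identifier.
#'
#' @param scores Real-valued score matrix, same shape/ids as `training`.
#' @param training Binary training association matrix.
#' @param path Output TSV path.
#' @param top_k Number of candidates kept per drug.
#' @return Invisibly, the ranked data frame that was written.
#' @export
write_ranked_predictions <- function(scores, training, path, top_k = 10L) {
  stopifnot(is.matrix(scores), is.matrix(training))
  if (!identical(dim(scores), dim(training))) {
    stop("scores and training matrices differ in shape", call. = FALSE)
  }
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    keep <- which(training[i, ] == 0)
    if (!length(keep)) return(NULL)
    ids <- colnames(scores)[keep]
    sc <- scores[i, keep]
    ord <- order(-sc, ids)
    ord <- ord[seq_len(min(top_k, length(ord)))]
    data.frame(
      drug_id = rownames(scores)[[i]],
      disease_id = ids[ord],
      score = unname(sc[ord]),
      rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
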