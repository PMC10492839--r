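#' Read a labelled matrix from a tab-separated file
#'
#' Reads a numeric matrix with one header row and one leading id column,
#' optionally gzip-compressed. This is the on-disk format used for all
#' gene-by-entity inputs: TWAS z-score and p-value matrices, drug
#' perturbation profiles, and projected matrices.
#'
#' @param path Path to a tab-separated file (`.tsv` or `.tsv.gz`).
#' @param orientation What the rows of the file are: `"genes"` (the default
#'   for projection inputs) or `"traits"`. Recorded as an attribute; no
#'   transposition is performed.
#' @return A numeric matrix with row and column names taken from the file,
#'   in file order, and an `"orientation"` attribute.
#' @export
read_labelled_matrix <- function(path, orientation = c("genes", "traits")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    dt <- data.table::fread(text = readLines(con), sep = "\t",
                            header = TRUE, data.table = FALSE)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
  }
  if (ncol(dt) < 2L) {
    stop("expected an id column plus at least one data column in ", path)
  }
  row_ids <- as.character(dt[[1L]])
  col_ids <- colnames(dt)[-1L]
  assert_unique_ids(row_ids, "row")
  assert_unique_ids(col_ids, "column")
  vals <- matrix(NA_real_, nrow(dt), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    col <- dt[[j + 1L]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")[1L]
      if (!is.na(bad)) {
        stop("non-numeric value ", sQuote(col[bad]), " at row ",
             sQuote(row_ids[bad]), ", column ", sQuote(col_ids[j]),
             " in ", path)
      }
      col <- num
    }
    vals[, j] <- col
  }
  attr(vals, "orientation") <- orientation
  vals
}

#' Write a labelled matrix to a tab-separated file
#'
#' Inverse of [read_labelled_matrix()]; `read(write(x))` restores values and
#' ids exactly up to floating-point text round-trip. Paths ending in `.gz`
#' are gzip-compressed.
#'
#' @param x A numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_labelled_matrix <- function(x, path, id_col = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t", compress = "auto")
  invisible(path)
}

#' Align a genes-by-entities matrix to a latent model's gene axis
#'
#' Reorders the rows of `m` to the model's gene order. Genes present in `m`
#' but absent from the model are always dropped (with a message). Model
#' genes absent from `m` are either filled with zero rows
#' (`policy = "zero_fill"`, the default: a zero z-score is neutral in the
#' projection dot products) or dropped from the output
#' (`policy = "intersect"`; downstream consumers subset the loading matrix
#' to the surviving genes).
#'
#' @param m A matrix with genes as rows (see [read_labelled_matrix()]).
#' @param model A [latent_model()].
#' @param policy `"zero_fill"` or `"intersect"`.
#' @return The aligned matrix. Under `zero_fill` its row count always equals
#'   the model gene count and the number of inserted rows is recorded in the
#'   `"n_zero_filled"` attribute.
#' @export
align_genes <- function(m, model, policy = c("zero_fill", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(m))
  model_genes <- rownames(model$Z)
  if (nrow(m) == 0L || is.null(rownames(m)) ||
      length(setdiff(rownames(m), model_genes)) == nrow(m)) {
    stop("no genes shared between the matrix and the latent model")
  }
  extra <- setdiff(rownames(m), model_genes)
  if (length(extra) > 0L) {
    rlang::inform(paste0("align_genes: dropping ", length(extra),
                         " gene(s) absent from the latent model"))
    m <- m[setdiff(rownames(m), extra), , drop = FALSE]
  }
  missing <- setdiff(model_genes, rownames(m))
  if (policy == "zero_fill") {
    if (length(missing) > 0L) {
      fill <- matrix(0, length(missing), ncol(m),
                     dimnames = list(missing, colnames(m)))
      m <- rbind(m, fill)
      rlang::inform(paste0("align_genes: zero-filling ", length(missing),
                           " model gene(s) absent from the matrix"))
    }
    out <- m[model_genes, , drop = FALSE]
    attr(out, "n_zero_filled") <- length(missing)
  } else {
    keep <- intersect(model_genes, rownames(m))
    if (length(keep) == 0L) {
      stop("empty gene intersection between the matrix and the latent model")
    }
    out <- m[keep, , drop = FALSE]
    attr(out, "n_zero_filled") <- 0L
  }
  attr(out, "alignment_policy") <- policy
  out
}

assert_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicated ", what, " id(s): ", paste(sQuote(dup), collapse = ", "))
  }
  invisible(ids)
}
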