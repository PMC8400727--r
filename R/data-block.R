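#' Create a data block
#'
#' A block is one dense numeric matrix taking part in a joint factorization.
#' After loading, the *matched* axis (the entities shared by all blocks —
#' samples in sample-matched mode, features such as genes in feature-matched
#' mode) is always the rows; blocks whose matched axis arrived as columns are
#' transposed by [load_blocks()] and tagged with
#' `orientation = "transposed"`.
#'
#' @param values Numeric matrix, no missing values.
#' @param name Block name (e.g. `"GE"`, `"DM"`).
#' @param row_ids,col_ids Entity identifiers; default to dimnames or
#'   generated ids.
#' @param orientation `"as_is"` or `"transposed"` — whether the loader
#'   transposed the raw file to put the matched axis on rows.
#' @return An object of class `data_block`.
#' @export
data_block <- function(values, name = "block",
                       row_ids = NULL, col_ids = NULL,
                       orientation = c("as_is", "transposed")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("block '", name, "': values must be numeric", call. = FALSE)
  if (anyNA(values)) stop("block '", name, "': missing values are not allowed", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("block '", name, "': need at least 2 rows and 2 columns", call. = FALSE)
  }
  row_ids <- row_ids %||% rownames(values) %||% paste0("r", seq_len(nrow(values)))
  col_ids <- col_ids %||% colnames(values) %||% paste0("c", seq_len(ncol(values)))
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    stop("block '", name, "': id lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(values) <- list(row_ids, col_ids)
  if (stats::sd(values) == 0) {
    warning("block '", name, "' has zero variance", call. = FALSE)
  }
  structure(
    list(name = name, values = values,
         row_ids = as.character(row_ids), col_ids = as.character(col_ids),
         orientation = orientation),
    class = "data_block"
  )
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block '%s'> %d x %d (%s)\n",
              x$name, nrow(x$values), ncol(x$values), x$orientation))
  invisible(x)
}

#' @export
dim.data_block <- function(x) dim(x$values)

# normalise `blocks` arguments: a single matrix/block or a list of them;
# verifies the matched axis (rows) is identical and identically ordered
as_block_list <- function(blocks) {
  if (is.matrix(blocks) || inherits(blocks, "data_block")) blocks <- list(blocks)
  if (!is.list(blocks) || length(blocks) == 0L) {
    stop("blocks must be a data_block/matrix or a non-empty list of them", call. = FALSE)
  }
  nm <- names(blocks) %||% rep("", length(blocks))
  blocks <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (inherits(b, "data_block")) return(b)
    data_block(b, name = if (nzchar(nm[i])) nm[i] else paste0("block", i))
  })
  ids <- blocks[[1L]]$row_ids
  for (b in blocks[-1L]) {
    if (!identical(b$row_ids, ids)) {
      bad <- utils::head(setdiff(union(ids, b$row_ids), intersect(ids, b$row_ids)), 5L)
      stop("matched-axis ids differ between blocks '", blocks[[1L]]$name,
           "' and '", b$name, "'",
           if (length(bad)) paste0(" (e.g. ", paste(bad, collapse = ", "), ")"),
           call. = FALSE)
    }
  }
  blocks
}

`%||%` <- function(a, b) if (is.null(a)) b else a
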