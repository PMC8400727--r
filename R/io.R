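#' Read a numeric matrix from TSV/CSV
#'
#' First row = column identifiers, first column = row identifiers, dense
#' numeric body. The separator is taken from the file extension (`.csv`
#' means comma, anything else tab). Any missing or non-numeric cell is an
#' error naming its coordinates.
#'
#' @param path File path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    suppressWarnings(storage.mode(M) <- "double")
  }
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop("missing or non-numeric cell at row '", rownames(M)[bad[1L]],
         "', column '", colnames(M)[bad[2L]], "' in ", path, call. = FALSE)
  }
  M
}

#' Write a numeric matrix as TSV
#'
#' @param M Matrix with dimnames.
#' @param path Output path.
#' @param id_name Header of the row-identifier column.
#' @export
write_matrix <- function(M, path, id_name = "id") {
  df <- data.frame(rownames(M) %||% as.character(seq_len(nrow(M))),
                   M, check.names = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load data blocks from a manifest
#'
#' The manifest (YAML or JSON file, or an equivalent list) has a `blocks`
#' entry; each block gives `file`, `name`, and `matched_axis`
#' (`"rows"` or `"columns"`). Blocks whose matched axis is columns are
#' transposed so the matched entities always end up on rows, and all blocks
#' are checked (and reordered where needed) to share the same matched-axis
#' identifiers in the same order.
#'
#' @param manifest Path to a YAML/JSON manifest, or a list with a `blocks`
#'   element.
#' @param base_dir Directory paths in the manifest are relative to
#'   (defaults to the manifest's directory).
#' @return A list of `data_block`s.
#' @export
load_blocks <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- if (grepl("\\.json$", manifest, ignore.case = TRUE)) {
      jsonlite::read_json(manifest, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(manifest)
    }
  }
  base_dir <- base_dir %||% "."
  specs <- manifest$blocks
  if (is.null(specs) || length(specs) == 0L) {
    stop("manifest must list at least one block", call. = FALSE)
  }
  blocks <- lapply(specs, function(sp) {
    axis <- sp$matched_axis %||% "rows"
    if (!axis %in% c("rows", "columns")) {
      stop("matched_axis must be 'rows' or 'columns' for block '",
           sp$name %||% sp$file, "'", call. = FALSE)
    }
    path <- sp$file
    if (!file.exists(path)) path <- file.path(base_dir, sp$file)
    M <- read_matrix(path)
    if (axis == "columns") {
      data_block(t(M), name = sp$name %||% basename(sp$file),
                 orientation = "transposed")
    } else {
      data_block(M, name = sp$name %||% basename(sp$file))
    }
  })
  ref <- blocks[[1L]]$row_ids
  blocks <- lapply(blocks, function(b) {
    if (identical(b$row_ids, ref)) return(b)
    if (setequal(b$row_ids, ref)) {
      b$values <- b$values[ref, , drop = FALSE]
      b$row_ids <- ref
      return(b)
    }
    bad <- utils::head(setdiff(union(ref, b$row_ids), intersect(ref, b$row_ids)), 5L)
    stop("matched-axis ids of block '", b$name, "' do not match (e.g. ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  })
  blocks
}

#' Save / load a fitted model as a directory of TSV files
#'
#' Writes `U.tsv`, one `Z_<block>_<n>.tsv` per block and layer, one
#' `H_<block>.tsv` (deepest latent) per block, and a `model.json` sidecar
#' holding the configuration, block names, identifiers, and training trace.
#' `load_model(save_model(m, dir))` reproduces the objective exactly.
#'
#' @param model A `jdsnmf_model`.
#' @param dir Output directory (created if missing).
#' @return `save_model()`: `dir`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  U <- model$U
  rownames(U) <- model$row_ids
  colnames(U) <- paste0("dim", seq_len(ncol(U)))
  write_matrix(U, file.path(dir, "U.tsv"))
  N <- model$config$n_layers
  for (i in seq_along(model$block_names)) {
    bn <- model$block_names[[i]]
    if (N > 0L) for (n in seq_len(N)) {
      Z <- model$Z[[i]][[n]]
      dimnames(Z) <- list(paste0("k", seq_len(nrow(Z))), paste0("k", seq_len(ncol(Z))))
      write_matrix(Z, file.path(dir, sprintf("Z_%s_%d.tsv", bn, n)))
    }
    H <- model$H[[i]]
    dimnames(H) <- list(paste0("k", seq_len(nrow(H))), model$col_ids[[i]])
    write_matrix(H, file.path(dir, sprintf("H_%s.tsv", bn)))
  }
  sidecar <- list(
    config = unclass(model$config),
    block_names = as.list(model$block_names),
    row_ids = model$row_ids,
    col_ids = model$col_ids,
    trace = if (!is.null(model$trace)) {
      c(as.list(model$trace),
        list(stopped_early = isTRUE(attr(model$trace, "stopped_early")),
             best_epoch = attr(model$trace, "best_epoch")))
    }
  )
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  side_path <- file.path(dir, "model.json")
  if (!file.exists(side_path)) stop("missing model.json in ", dir, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  cfg <- side$config
  config <- model_config(dims = unlist(cfg$dims), activation = cfg$activation,
                         l2_lambda = cfg$l2_lambda,
                         learning_rate = cfg$learning_rate,
                         max_epochs = cfg$max_epochs, patience = cfg$patience,
                         tol = cfg$tol, seed = cfg$seed)
  K <- config$dims
  N <- config$n_layers
  need <- function(path) {
    if (!file.exists(path)) stop("missing factor file: ", path, call. = FALSE)
    unname(read_matrix(path))
  }
  U <- need(file.path(dir, "U.tsv"))
  if (ncol(U) != K[1L]) {
    stop("integrity error: U has ", ncol(U), " columns but dims say ", K[1L],
         call. = FALSE)
  }
  block_names <- unlist(side$block_names)
  Z <- vector("list", length(block_names))
  H <- vector("list", length(block_names))
  for (i in seq_along(block_names)) {
    bn <- block_names[[i]]
    Z[[i]] <- if (N > 0L) lapply(seq_len(N), function(n) {
      Zn <- need(file.path(dir, sprintf("Z_%s_%d.tsv", bn, n)))
      if (!all(dim(Zn) == c(K[n], K[n + 1L]))) {
        stop("integrity error: Z_", bn, "_", n, " has shape ",
             paste(dim(Zn), collapse = "x"), " but dims say ",
             K[n], "x", K[n + 1L], call. = FALSE)
      }
      Zn
    }) else list()
    H[[i]] <- need(file.path(dir, sprintf("H_%s.tsv", bn)))
    if (nrow(H[[i]]) != K[N + 1L]) {
      stop("integrity error: H_", bn, " has ", nrow(H[[i]]),
           " rows but dims say ", K[N + 1L], call. = FALSE)
    }
  }
  trace <- NULL
  if (!is.null(side$trace)) {
    tr <- side$trace
    extra <- c("stopped_early", "best_epoch")
    trace <- tibble::as_tibble(tr[setdiff(names(tr), extra)])
    attr(trace, "stopped_early") <- isTRUE(tr$stopped_early)
    attr(trace, "best_epoch") <- tr$best_epoch
  }
  new_jdsnmf_model(U = U, Z = Z, H = H, config = config,
                   block_names = block_names,
                   row_ids = unlist(side$row_ids),
                   col_ids = lapply(side$col_ids, unlist),
                   trace = trace)
}
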