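# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# Convert a sample-by-feature tibble (first column = sample id) to a numeric
# matrix with sample ids as rownames.
block_to_matrix <- function(block, id_col = "sample_id") {
  if (is.matrix(block)) return(block)
  stopifnot(is.data.frame(block))
  if (!id_col %in% names(block)) {
    # assume first column holds sample ids
    id_col <- names(block)[1]
  }
  ids <- as.character(block[[id_col]])
  m <- as.matrix(block[, setdiff(names(block), id_col), drop = FALSE])
  if (!is.numeric(m)) {
    rlang::abort("Feature columns must be numeric.")
  }
  rownames(m) <- ids
  m
}

matrix_to_block <- function(m, id_col = "sample_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

# Coerce blocks argument: a single data frame becomes a one-element list.
as_block_list <- function(blocks) {
  if (is.data.frame(blocks) || is.matrix(blocks)) blocks <- list(blocks)
  ok <- vapply(blocks, function(b) is.data.frame(b) || is.matrix(b),
               logical(1))
  if (!is.list(blocks) || !all(ok)) {
    rlang::abort("`blocks` must be a data frame or a list of data frames.")
  }
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- paste0("block", seq_along(blocks))
  }
  blocks
}

# Encode an outcome as centred numeric {0,1} (binary) or centred numeric.
encode_outcome <- function(y) {
  if (is.data.frame(y)) {
    y <- y[[ncol(y)]]
  }
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    if (nlevels(y) != 2) {
      rlang::abort("Factor outcomes must have exactly 2 levels.")
    }
    enc <- as.numeric(y) - 1
    list(values = enc, levels = levels(y), binary = TRUE)
  } else if (is.numeric(y)) {
    u <- unique(y)
    if (length(u) == 2) {
      lev <- sort(u)
      list(values = as.numeric(y == lev[2]), levels = as.character(lev),
           binary = TRUE)
    } else {
      list(values = as.numeric(y), levels = NULL, binary = FALSE)
    }
  } else {
    rlang::abort("Outcome must be numeric, character or factor.")
  }
}

# Rank-based AUROC with midrank tie handling; positive class = larger label.
rank_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic child seeds derived from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Stratified fold assignment for a binary outcome; returns integer fold ids.
stratified_folds <- function(y, n_folds) {
  enc <- encode_outcome(y)
  if (!enc$binary) {
    return(sample(rep_len(seq_len(n_folds), length(enc$values))))
  }
  fold <- integer(length(enc$values))
  for (cls in unique(enc$values)) {
    idx <- which(enc$values == cls)
    if (length(idx) < n_folds) {
      rlang::abort("Each class must have at least `n_folds` members.")
    }
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
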