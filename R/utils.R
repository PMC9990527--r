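# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# min-max normalization to [0, 1]; constant input maps to all zeros
minmax <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) <= 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

# run-length encoding of a label vector into half-open [start, end) bouts
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  end <- cumsum(r$lengths)
  start <- c(0L, head(end, -1L))
  data.frame(behavior = r$values, start_frame = start, end_frame = end,
             stringsAsFactors = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# symmetric inverse square root with optional ridge for rank deficiency
inv_sqrtm <- function(M, ridge = 0) {
  e <- eigen(symm(M), symmetric = TRUE)
  v <- e$values
  if (any(v < 1e-10 * max(v))) {
    v <- v + ridge + 1e-10 * max(v)
  }
  e$vectors %*% diag(1 / sqrt(v), length(v)) %*% t(e$vectors)
}

symm <- function(M) (M + t(M)) / 2
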