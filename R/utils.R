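# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sectionmap <- function(msg, class) {
  stop(structure(class = c(class, "sectionmap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_sectionmap(sprintf("%s must be a numeric matrix", what), "value_error")
  }
  invisible(x)
}

# Replicate border rows/cols outward by k pixels.
pad_replicate <- function(m, k) {
  if (k == 0L) return(m)
  m[c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k)),
    c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
}

# Integer apportionment of `total` by `proportions` (largest remainder),
# so fixture cell counts are exact, not a multinomial draw.
apportion_counts <- function(total, proportions) {
  stopifnot(total >= 0, all(proportions >= 0))
  p <- proportions / sum(proportions)
  raw <- total * p
  counts <- floor(raw)
  short <- total - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

# Shift a matrix by integer (d_row, d_col), filling vacated pixels with `fill`.
shift_matrix <- function(m, d_row, d_col, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - d_row
  src_c <- seq_len(nc) - d_col
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

# Centered moving average used for derivative and histogram smoothing.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  k <- rep(1 / window, window)
  n <- length(x)
  pad <- (window - 1L) %/% 2L
  xp <- c(rep(x[1L], pad), x, rep(x[n], window - 1L - pad))
  stats::filter(xp, k, sides = 2)[(pad + 1L):(pad + n)]
}
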