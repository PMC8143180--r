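# Independent oracles used to verify the package's implementations.
# Deliberately naive: recursion and exhaustive enumeration, no shared code
# with the implementation under test.

# Edit distance by memoized recursion over string suffixes.
brute_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (nchar(a) == 0L) {
      nchar(b)
    } else if (nchar(b) == 0L) {
      nchar(a)
    } else {
      ca <- substr(a, 1, 1); cb <- substr(b, 1, 1)
      ra <- substr(a, 2, nchar(a)); rb <- substr(b, 2, nchar(b))
      min(rec(ra, rb) + (ca != cb), rec(ra, b) + 1L, rec(a, rb) + 1L)
    }
    memo[[key]] <- val
    val
  }
  rec(a, b)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Exact two-sided rank-sum p-value by enumerating all group labelings.
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Hand-stepped Holm adjustment: sort, multiply by (m - i + 1), enforce
# monotonicity, cap at 1, restore input order.
hand_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- stepped
  out
}

# A deterministic threshold reader for staircase tests.
threshold_reader <- function(span, time_ms, ...) {
  sim_reader_params(true_span = span, threshold_time_ms = time_ms,
                    slope = Inf, ...)
}
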