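# Independent oracles used to check package computations. These share no
# code with the implementation paths they verify.

# Two-sided Fisher p by direct enumeration of all tables with the observed
# margins, from binomial coefficients (minimum-likelihood rule).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  N <- r1 + r2
  if (N == 0) return(1)
  xs <- max(0, k - r2):min(r1, k)
  pr <- choose(r1, xs) * choose(r2, k - xs) / choose(N, k)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(N, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# BH step-up computed the long way: sort, scale by n/i, enforce
# monotonicity from the largest p down, cap at 1, restore input order.
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Aggregate signal by per-base summation over MSP rows (no difference
# array): fibers is a fiber_set, all on one chromosome.
signal_by_base <- function(fibers, chrom, start, end) {
  msps <- fibers$msps
  idx <- match(msps$fiber_id, fibers$fibers$fiber_id)
  msps <- msps[fibers$fibers$chrom[idx] == chrom, , drop = FALSE]
  pos <- seq(start, end - 1)
  vapply(pos, function(g) {
    hit <- msps$start <= g & g < msps$end
    if (!any(hit)) return(0)
    sum(-10 * log10(pmax(1 - msps$precision[hit], 1e-10)))
  }, numeric(1))
}

# Maximal runs of TRUE in a logical vector, as (start0, end0) half-open
# offsets, by scanning indices.
runs_of <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(data.frame(start = integer(), end = integer()))
  brk <- c(0, which(diff(idx) > 1), length(idx))
  data.frame(start = idx[head(brk, -1) + 1] - 1L,
             end = idx[brk[-1]])
}

# Brute-force per-peak haplotype counts: explicit double loop over
# (fiber, peak), re-deriving spanning and accessibility from raw tables.
counts_by_loop <- function(fibers, peaks, min_precision) {
  fib <- fibers$fibers
  msps <- fibers$msps
  out <- data.frame(peak_id = peaks$peak_id, acc_h1 = 0L, total_h1 = 0L,
                    acc_h2 = 0L, total_h2 = 0L)
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(fib))) {
      if (fib$haplotype[j] == "UNASSIGNED") next
      if (fib$chrom[j] != peaks$chrom[i]) next
      if (!(fib$start[j] <= peaks$start[i] &&
              peaks$end[i] <= fib$end[j])) next
      m <- msps[msps$fiber_id == fib$fiber_id[j], , drop = FALSE]
      open <- any(m$precision >= min_precision &
                    m$start < peaks$end[i] & peaks$start[i] < m$end)
      h <- fib$haplotype[j]
      if (h == "H1") {
        out$total_h1[i] <- out$total_h1[i] + 1L
        if (open) out$acc_h1[i] <- out$acc_h1[i] + 1L
      } else {
        out$total_h2[i] <- out$total_h2[i] + 1L
        if (open) out$acc_h2[i] <- out$acc_h2[i] + 1L
      }
    }
  }
  out
}
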