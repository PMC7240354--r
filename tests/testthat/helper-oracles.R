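# Independent oracles, deliberately naive: day-by-day counting, O(n^2)
# pairwise statistics, dense grid search. They share no code with the
# package implementations they check.

# MPR by iterating over every calendar day of the segment and asking whether
# any prescription interval [date, date + supply) covers it.
oracle_mpr <- function(dates, supplies) {
  start <- min(dates)
  end <- max(dates + supplies)
  covered <- vapply(start:(end - 1L), function(day)
    any(day >= dates & day < dates + supplies), logical(1))
  mean(covered)
}

# AUC as the literal pairwise concordance probability, ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Dense grid search for the K = 2 MAP document-topic problem: pi = (g, 1-g).
oracle_doc_topics_k2 <- function(x, phi, alpha = 1, by = 1e-5) {
  grid <- seq(0, 1, by = by)
  m <- outer(grid, phi[1L, ]) + outer(1 - grid, phi[2L, ])
  ll <- log(pmax(m, 1e-9)) %*% x
  if (alpha != 1) {
    ll <- ll + (alpha - 1) * (log(pmax(grid, 1e-12)) + log(pmax(1 - grid, 1e-12)))
  }
  grid[which.max(ll)]
}

# Best topic alignment over all permutations (exact Hungarian for small K):
# mean row-wise L1 distance after the optimal row matching.
oracle_topic_alignment <- function(est, truth) {
  K <- nrow(truth)
  perms <- permutations_of(K)
  best <- Inf
  for (p in perms) {
    d <- mean(rowSums(abs(est[p, , drop = FALSE] - truth)))
    if (d < best) best <- d
  }
  best
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  # place K at every position within each permutation of 1..K-1
  for (p in permutations_of(K - 1L)) for (pos in seq_len(K)) {
    q <- integer(K); q[pos] <- K; q[-pos] <- p
    out[[length(out) + 1L]] <- q
  }
  out
}

# tiny hand-rolled prescription tables for rule-boundary cases
rx_table <- function(dates, supply, drug = "drug_a") {
  data.frame(date = as.integer(dates), drug_name = drug,
             days_supply = as.integer(rep_len(supply, length(dates))),
             stringsAsFactors = FALSE)
}
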