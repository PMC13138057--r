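# Independent reference implementations used as oracles. Each is a direct
# transcription of the textbook definition, kept separate from the package
# code paths it checks.

# Brute-force DBSCAN from the definition: core points have >= min_samples
# points (self included) within eps; clusters are the connected components
# of core points under the eps relation; border points join their nearest
# core's cluster; everything else is noise.
oracle_dbscan <- function(x, y, eps, min_samples) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  adj <- d2 <= eps^2
  core <- rowSums(adj) >= min_samples
  lab <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != -1L) next
    cl <- cl + 1L
    members <- i
    repeat {
      reach <- which(core & lab == -1L &
                       apply(adj[members, , drop = FALSE], 2, any))
      reach <- setdiff(reach, members)
      if (length(reach) == 0) break
      lab[reach] <- cl
      members <- c(members, reach)
    }
    lab[i] <- cl
  }
  for (i in seq_len(n)) {
    if (core[i]) next
    cores_near <- which(core & adj[i, ])
    if (length(cores_near) == 0) next
    nearest <- cores_near[order(d2[i, cores_near], lab[cores_near])][1]
    lab[i] <- lab[nearest]
  }
  lab
}

# Canonical form of a label vector: clusters renumbered by first
# occurrence, noise kept at -1, so two labelings of the same partition
# compare equal.
canonical_labels <- function(lab) {
  seen <- unique(lab[lab >= 0])
  out <- lab
  for (i in seq_along(seen)) out[lab == seen[i]] <- i - 1L
  out
}

# Exhaustive active-set NNLS: enumerate all 2^k support patterns, solve
# unconstrained least squares on each support, keep the feasible solution
# with the smallest residual norm.
oracle_nnls <- function(x, W) {
  k <- ncol(W)
  best <- rep(0, k)
  best_obj <- sum(x^2)
  for (mask in seq_len(2^k) - 1L) {
    s <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(s) == 0) next
    h <- tryCatch(qr.solve(W[, s, drop = FALSE], x), error = function(e) NULL)
    if (is.null(h) || any(h < 0)) next
    obj <- sum((x - W[, s, drop = FALSE] %*% h)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- rep(0, k)
      best[s] <- h
    }
  }
  best
}

# Textbook chi-squared: E = row * col / N, X2 = sum (O-E)^2/E,
# dof = (r-1)(c-1), Pearson residuals (O-E)/sqrt(E).
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  dof <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, dof = dof,
       p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
       residuals = (tab - E) / sqrt(E))
}

# Exact two-sided rank-sum p by full enumeration of all C(n+m, n) group
# assignments of the pooled ranks.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(x)
  obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Map fitted identity labels to planted labels by the permutation of
# factor names maximizing agreement; returns the achieved agreement rate
# and the mapping.
match_identities <- function(fitted, truth) {
  f_levels <- sort(unique(truth))
  perms <- combinat_perms(f_levels)
  best <- list(rate = -1, map = NULL)
  for (p in perms) {
    map <- stats::setNames(p, f_levels)
    remapped <- unname(map[fitted])
    rate <- mean(!is.na(remapped) & remapped == truth)
    if (rate > best$rate) best <- list(rate = rate, map = map)
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
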