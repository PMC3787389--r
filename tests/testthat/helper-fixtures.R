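# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# small random descriptor matrix with ids
rand_descriptors <- function(n, p, seed = 1, prefix = "c") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                         sprintf("d%02d", seq_len(p))))
}

# single-receptor activity matrix from a response vector
activity_of <- function(responses, receptor = "OrA",
                        odor_ids = sprintf("c%02d", seq_along(responses))) {
  matrix(responses, ncol = 1, dimnames = list(odor_ids, receptor))
}

# independent brute-force objective: literally build both full matrices
# and a flat pair list with double loops
oracle_objective <- function(descriptors, multiset, activity_vec, active_ids) {
  ids <- sort(rownames(descriptors))
  w <- table(as.character(multiset))
  n <- length(ids)
  cbcd <- matrix(0, n, n, dimnames = list(ids, ids))
  cbca <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ids) for (j in ids) {
    s <- 0
    for (k in names(w)) s <- s + w[[k]] * (descriptors[i, k] - descriptors[j, k])^2
    cbcd[i, j] <- sqrt(s)
    cbca[i, j] <- abs(activity_vec[i] - activity_vec[j])
  }
  v1 <- c(); v2 <- c()
  for (i in sort(active_ids)) for (j in ids) {
    if (i == j) next
    v1 <- c(v1, cbcd[i, j]); v2 <- c(v2, cbca[i, j])
  }
  if (sd(v1) == 0 || sd(v2) == 0) return(-Inf)
  cor(v1, v2)
}

# exhaustive greedy oracle for the forward selection: at each step try
# every candidate by full recomputation through oracle_objective
oracle_sfs <- function(descriptors, activity_vec, active_ids, steps) {
  sel <- character(0)
  objs <- numeric(0)
  best <- -Inf
  for (s in seq_len(steps)) {
    cand_ids <- sort(colnames(descriptors))
    vals <- vapply(cand_ids, function(k) {
      oracle_objective(descriptors, c(sel, k), activity_vec, active_ids)
    }, numeric(1))
    k <- cand_ids[which.max(vals)]
    if (!(max(vals) > best)) break
    best <- max(vals)
    sel <- c(sel, k)
    objs <- c(objs, best)
  }
  list(sel = sel, objs = objs)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
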