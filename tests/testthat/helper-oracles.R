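# Brute-force oracles: direct loop/enumeration implementations of the
# network metrics, kept deliberately independent of the package's
# matrix-based code paths.

bf_density <- function(A) {
  n <- nrow(A)
  m <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j] == 1L) m <- m + 1L
  m / (n * (n - 1))
}

bf_centralization_in <- function(A) {
  n <- nrow(A)
  deg <- integer(n)
  for (j in seq_len(n)) for (i in seq_len(n))
    if (i != j && A[i, j] == 1L) deg[j] <- deg[j] + 1L
  sum(max(deg) - deg) / (n - 1)^2
}

bf_clustering <- function(A) {
  n <- nrow(A)
  total <- 0
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n))
      if (i != j && (A[i, j] == 1L || A[j, i] == 1L)) nb <- c(nb, j)
    k <- length(nb)
    if (k < 2L) next
    links <- 0L
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      u <- nb[a]; v <- nb[b]
      if (A[u, v] == 1L || A[v, u] == 1L) links <- links + 1L
    }
    total <- total + links / choose(k, 2)
  }
  total / n
}

bf_reciprocity <- function(A) {
  n <- nrow(A)
  m <- 0L; mut <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || A[i, j] == 0L) next
    m <- m + 1L
    if (A[j, i] == 1L) mut <- mut + 1L
  }
  if (m == 0L) return(NA_real_)
  mut / m
}

bf_coleman <- function(A, types, group) {
  n <- nrow(A)
  members <- which(types %in% group)
  n_g <- length(members)
  if (n_g == 0L || n_g == n) return(NA_real_)
  m <- 0L; within <- 0L
  for (i in members) for (j in seq_len(n)) {
    if (i == j || A[i, j] == 0L) next
    m <- m + 1L
    if (j %in% members) within <- within + 1L
  }
  if (m == 0L) return(NA_real_)
  w <- within / m
  e <- (n_g - 1) / (n - 1)
  if (w >= e) (w - e) / (1 - e) else (w - e) / e
}

bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
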