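# Independent oracles used to cross-check the production implementations.
# Both are deliberately written as different algorithms from the package's
# own code paths.

# 0-dimensional sublevel-set persistence by a union-find sweep over the
# sentinel-extended sequence [+Inf, f(1..n), -Inf] on a path graph, adding
# vertices in ascending tie-broken (value, index) order.  When a vertex
# bridges two existing components the younger one (larger birth key) dies
# there (elder rule).  Returns the multiset of finite (birth, death) value
# pairs with both vertices inside the signal.
uf_sublevel_diagram <- function(f) {
  n <- length(f)
  vals <- c(Inf, f, -Inf)                      # positions 1..n+2
  m <- n + 2L
  ord <- order(vals, seq_len(m))
  parent <- integer(m)
  birth <- integer(m)
  present <- logical(m)
  find <- function(x) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    while (parent[x] != r) { nx <- parent[x]; parent[x] <<- r; x <- nx }
    r
  }
  key_lt <- function(i, j) vals[i] < vals[j] || (vals[i] == vals[j] && i < j)
  births <- deaths <- numeric(0)
  for (v in ord) {
    lp <- v > 1L && present[v - 1L]
    rp <- v < m && present[v + 1L]
    present[v] <- TRUE
    if (!lp && !rp) {
      parent[v] <- v; birth[v] <- v
    } else if (lp && !rp) {
      parent[v] <- find(v - 1L)
    } else if (!lp && rp) {
      parent[v] <- find(v + 1L)
    } else {
      rl <- find(v - 1L); rr <- find(v + 1L)
      if (rl == rr) {
        parent[v] <- rl
      } else {
        older <- if (key_lt(birth[rl], birth[rr])) rl else rr
        younger <- if (identical(older, rl)) rr else rl
        bv <- birth[younger]
        if (bv >= 2L && bv <= n + 1L && v >= 2L && v <= n + 1L) {
          births <- c(births, vals[bv]); deaths <- c(deaths, vals[v])
        }
        parent[younger] <- older
        parent[v] <- older
      }
    }
  }
  cbind(birth = births, death = deaths)
}

# Sorted (birth, death) value matrix from any diagram representation, for
# multiset comparison.
sorted_pairs <- function(d) {
  m <- if (is.matrix(d)) d else cbind(d$birth, d$death)
  if (NROW(m) == 0) return(matrix(numeric(), 0, 2))
  m <- m[, 1:2, drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# Brute-force q-Wasserstein by exhaustive enumeration of augmented
# matchings: each point of A maps to an unused point of B or retires to the
# diagonal (L-inf cost (death-birth)/2); unmatched B points retire too.
bf_wasserstein <- function(A, B, q = 1) {
  A <- if (NROW(A)) as.matrix(A)[, 1:2, drop = FALSE] else matrix(numeric(), 0, 2)
  B <- if (NROW(B)) as.matrix(B)[, 1:2, drop = FALSE] else matrix(numeric(), 0, 2)
  na <- nrow(A); nb <- nrow(B)
  persA <- abs(A[, 2] - A[, 1]) / 2
  persB <- abs(B[, 2] - B[, 1]) / 2
  best <- Inf
  rec <- function(i, usedB, cost) {
    if (i > na) {
      total <- cost + sum(persB[!usedB]^q)
      if (total < best) best <<- total
      return(invisible())
    }
    rec(i + 1L, usedB, cost + persA[i]^q)
    for (j in seq_len(nb)) {
      if (!usedB[j]) {
        d <- max(abs(A[i, 1] - B[j, 1]), abs(A[i, 2] - B[j, 2]))
        usedB[j] <- TRUE
        rec(i + 1L, usedB, cost + d^q)
        usedB[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nb), 0)
  unname(best^(1 / q))
}

# Random test-case generators --------------------------------------------

random_signal <- function(max_len = 30, tie_prone = NA) {
  n <- sample(0:max_len, 1)
  if (is.na(tie_prone)) tie_prone <- runif(1) < 0.5
  if (tie_prone) sample(0:4, n, replace = TRUE) else round(runif(n, 0, 10), 3)
}

random_diagram <- function(max_pts = 4, scale = 5) {
  k <- sample(0:max_pts, 1)
  b <- round(runif(k, 0, scale), 2)
  d <- b + round(rexp(k, 1 / scale), 2)
  cbind(birth = b, death = d)
}
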