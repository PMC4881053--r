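# Independent oracles used across test files. These deliberately do not
# share code with the package implementation beyond the standard genetic
# code table.

.GC <- setNames(as.character(Biostrings::GENETIC_CODE),
                names(Biostrings::GENETIC_CODE))

# straightforward per-codon translation
oracle_translate <- function(dna, frame = 0) {
  n <- (nchar(dna) - frame) %/% 3
  if (n <= 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(dna, frame + 3 * i - 2, frame + 3 * i)
    out[i] <- if (cod %in% names(.GC)) .GC[[cod]] else "X"
  }
  paste(out, collapse = "")
}

# affine-gap Smith-Waterman on short peptides (O(n m) with explicit
# three-state recursion); returns the optimal score
oracle_sw <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[av[i - 1], bv[j - 1]]
    M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                              Iy[i - 1, j - 1]))
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                    Ix[i - 1, j] - gap_extend)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                    Iy[i, j - 1] - gap_extend)
    best <- max(best, M[i, j])
  }
  best
}

# NG86 by direct enumeration: potential sites per codon and
# pathway-averaged differences, written independently of the package
oracle_ng86 <- function(ca, cb) {
  bases <- c("A", "C", "G", "T")
  sites1 <- function(cod) {
    syn <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(cod, p, p))) {
      alt <- cod; substr(alt, p, p) <- b
      if (.GC[[alt]] == .GC[[cod]]) syn <- syn + 1 / 3
    }
    syn
  }
  paths <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    res <- list()
    recurse <- function(cur, left, sd, nd, allow) {
      if (length(left) == 0) { res[[length(res) + 1]] <<- c(sd, nd); return() }
      for (p in left) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (.GC[[nxt]] == "*" && !allow) next
        if (.GC[[nxt]] == .GC[[cur]])
          recurse(nxt, setdiff(left, p), sd + 1, nd, allow)
        else recurse(nxt, setdiff(left, p), sd, nd + 1, allow)
      }
    }
    recurse(c1, pos, 0, 0, FALSE)
    if (length(res) == 0) recurse(c1, pos, 0, 0, TRUE)
    m <- do.call(rbind, res)
    colMeans(m)
  }
  L <- nchar(ca) / 3
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(L)) {
    x <- substr(ca, 3 * i - 2, 3 * i)
    y <- substr(cb, 3 * i - 2, 3 * i)
    S <- S + (sites1(x) + sites1(y)) / 2
    pr <- paths(x, y)
    Sd <- Sd + pr[1]; Nd <- Nd + pr[2]
  }
  N <- 3 * L - S
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# exhaustive linear-cost parsimony over all ancestral assignments
oracle_sankoff <- function(tree, leaf_counts, smax) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):max(tree$edge)
  states <- 0:smax
  grids <- rep(list(states), length(internal))
  best_cost <- Inf
  best_roots <- integer(0)
  idx <- rep(1L, length(internal))
  repeat {
    assign_int <- states[idx]
    val <- c(leaf_counts[tree$tip.label], assign_int)
    names(val) <- c(tree$tip.label, as.character(internal))
    node_val <- function(v) if (v <= n_tip) leaf_counts[tree$tip.label[v]]
      else assign_int[v - n_tip]
    cost <- 0
    for (e in seq_len(nrow(tree$edge)))
      cost <- cost + abs(node_val(tree$edge[e, 1]) - node_val(tree$edge[e, 2]))
    root_state <- assign_int[1]
    if (cost < best_cost) { best_cost <- cost; best_roots <- root_state }
    else if (cost == best_cost) best_roots <- c(best_roots, root_state)
    # increment odometer
    k <- 1L
    while (k <= length(idx)) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= length(states)) break
      idx[k] <- 1L; k <- k + 1L
    }
    if (k > length(idx)) break
  }
  list(cost = best_cost, min_root = min(best_roots))
}

# simple random protein with the package's filler composition left aside:
# uniform over 20 amino acids
rand_protein <- function(n) {
  aas <- setdiff(unique(.GC[.GC != "*"]), character(0))
  paste0("M", paste(sample(aas, n - 1, replace = TRUE), collapse = ""))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate a fraction of residues of a protein to random other residues
mutate_protein <- function(p, frac) {
  aas <- unique(.GC[.GC != "*"])
  v <- strsplit(p, "")[[1]]
  k <- ceiling(frac * length(v))
  pos <- sample(length(v), k)
  for (i in pos) v[i] <- sample(setdiff(aas, v[i]), 1)
  paste(v, collapse = "")
}
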