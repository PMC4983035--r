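## Independent brute-force oracles. These deliberately avoid the package's
## own algorithms: windows are enumerated by substring inspection, alignments
## by explicit enumeration of every global alignment, parsimony by exhaustive
## ancestral labeling, and Mann-Whitney p-values by permutation enumeration.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, pool = AA20) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

## --- acidic window scan ----------------------------------------------------

brute_scan <- function(seq, window = 10, min_fraction = 0.8,
                       acidic = c("D", "E"), tail_len = 50) {
  L <- nchar(seq)
  if (L < window) {
    return(data.frame(start = integer(0), end = integer(0),
                      acidic_count = integer(0)))
  }
  region_start <- if (is.finite(tail_len)) max(1, L - tail_len + 1) else 1
  out <- list()
  for (s in region_start:(L - window + 1)) {
    win <- strsplit(substr(seq, s, s + window - 1), "")[[1]]
    cnt <- sum(win %in% acidic)
    if (cnt / window >= min_fraction) {
      out[[length(out) + 1]] <- data.frame(start = s, end = s + window - 1,
                                           acidic_count = cnt)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), acidic_count = integer(0))
}

## --- global alignment ------------------------------------------------------

## every global alignment of a and b as pairs of gapped character vectors
enumerate_alignments <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) {
      return(list(list(a = character(0), b = character(0))))
    }
    outs <- list()
    if (i <= length(ca) && j <= length(cb)) {
      for (al in rec(i + 1, j + 1)) {
        outs[[length(outs) + 1]] <- list(a = c(ca[i], al$a), b = c(cb[j], al$b))
      }
    }
    if (i <= length(ca)) {
      for (al in rec(i + 1, j)) {
        outs[[length(outs) + 1]] <- list(a = c(ca[i], al$a), b = c("-", al$b))
      }
    }
    if (j <= length(cb)) {
      for (al in rec(i, j + 1)) {
        outs[[length(outs) + 1]] <- list(a = c("-", al$a), b = c(cb[j], al$b))
      }
    }
    outs
  }
  rec(1, 1)
}

## affine score of one alignment: substitution scores minus, per maximal gap
## run, (open + len * ext) — the same convention Biostrings uses
score_alignment <- function(al, submat, open, ext) {
  sub <- 0
  for (k in seq_along(al$a)) {
    if (al$a[k] != "-" && al$b[k] != "-") sub <- sub + submat[al$a[k], al$b[k]]
  }
  gapcost <- function(row) {
    r <- rle(row == "-")
    sum(vapply(r$lengths[r$values], function(L) open + L * ext, numeric(1)))
  }
  sub - gapcost(al$a) - gapcost(al$b)
}

brute_best_score <- function(a, b, submat, open = 10, ext = 0.5) {
  max(vapply(enumerate_alignments(a, b), score_alignment, numeric(1),
             submat = submat, open = open, ext = ext))
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

## --- parsimony -------------------------------------------------------------

## minimum number of state changes over all internal labelings
brute_fitch <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  st <- as.integer(states[tree$tip.label])
  nint <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- c(st, as.integer(intToBits(mask))[seq_len(nint)])
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  as.integer(best)
}

## minimum gains with losses forbidden: labelings without any 1->0 edge,
## cost = number of 0->1 edges plus one if the root itself is in state 1
brute_gains_only <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  st <- as.integer(states[tree$tip.label])
  nint <- tree$Nnode
  root <- ntip + 1
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- c(st, as.integer(intToBits(mask))[seq_len(nint)])
    up <- lab[tree$edge[, 1]]
    dn <- lab[tree$edge[, 2]]
    if (any(up == 1 & dn == 0)) next
    best <- min(best, sum(up == 0 & dn == 1) + lab[root])
  }
  as.integer(best)
}

## minimum events under exactly one gain: labelings with exactly one gain
## event (a 0->1 edge, or the root starting in state 1), cost = 1 + losses
brute_dollo_events <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  st <- as.integer(states[tree$tip.label])
  if (all(st == 0)) return(0L)
  nint <- tree$Nnode
  root <- ntip + 1
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- c(st, as.integer(intToBits(mask))[seq_len(nint)])
    up <- lab[tree$edge[, 1]]
    dn <- lab[tree$edge[, 2]]
    gains <- sum(up == 0 & dn == 1) + lab[root]
    if (gains != 1) next
    best <- min(best, 1 + sum(up == 1 & dn == 0))
  }
  as.integer(best)
}

random_binary_states <- function(tree) {
  st <- sample(0:1, ape::Ntip(tree), replace = TRUE)
  stats::setNames(st, tree$tip.label)
}

## a few fixed multifurcating topologies for generalized-Fitch checks
polytomy_trees <- function() {
  lapply(c("((A,B,C),(D,E));",
           "(A,B,C,D,E);",
           "((A,B),(C,D,E,F),G);"),
         function(s) ape::read.tree(text = s))
}

## --- Mann-Whitney ----------------------------------------------------------

## exact two-sided p by enumerating all group assignments of the pooled
## values (doubled smaller tail, capped at 1 — the exact-test convention)
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  idx <- utils::combn(n, na)
  ustat <- function(sel) {
    ga <- pooled[sel]
    gb <- pooled[-sel]
    sum(outer(ga, gb, ">")) + 0.5 * sum(outer(ga, gb, "=="))
  }
  u_obs <- ustat(seq_len(na))
  us <- apply(idx, 2, ustat)
  mu <- na * (n - na) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

## --- misc ------------------------------------------------------------------

make_balanced16 <- function() {
  ape::read.tree(text = paste0(
    "((((t1,t2),(t3,t4)),((t5,t6),(t7,t8))),",
    "(((t9,t10),(t11,t12)),((t13,t14),(t15,t16))));"))
}

scattered_states16 <- function() {
  st <- stats::setNames(rep(0L, 16), paste0("t", 1:16))
  st[c("t1", "t2", "t5", "t6", "t9", "t10", "t13", "t14")] <- 1L
  st
}
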