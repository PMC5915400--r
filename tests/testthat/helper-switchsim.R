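# Shared helpers: hand-built lattices and small independent oracles.

# Build a Lattice from plain matrices; strategy/phase default from matingType.
makeLattice <- function(matingType, strategy = NULL, switchPhase = NULL,
                        cloneId = NULL, intraclonal = NULL,
                        boundary = "bounded") {
  mt <- matrix(as.integer(matingType), nrow(matingType), ncol(matingType))
  occ <- mt != 0L
  z <- matrix(0L, nrow(mt), ncol(mt))
  st <- if (is.null(strategy)) {
    s <- z; s[occ] <- 2L; s  # default: non-switchers
  } else matrix(as.integer(strategy), nrow(mt), ncol(mt))
  ph <- if (is.null(switchPhase)) {
    p <- z; p[occ & st == 1L] <- 1L; p
  } else matrix(as.integer(switchPhase), nrow(mt), ncol(mt))
  cl <- if (is.null(cloneId)) {
    cc <- z; cc[occ] <- seq_len(sum(occ)); cc
  } else matrix(as.integer(cloneId), nrow(mt), ncol(mt))
  ic <- if (is.null(intraclonal)) z
        else matrix(as.integer(intraclonal), nrow(mt), ncol(mt))
  new("Lattice", matingType = mt, strategy = st, switchPhase = ph,
      cloneId = cl, intraclonal = ic, mated = z, boundary = boundary)
}

# Construct a MatingOutcome directly from parent strategy pairs and
# intraclonal flags (for testing the gamete-pool arithmetic in isolation).
makeOutcome <- function(strategyA, strategyB, intraclonal = FALSE) {
  n <- length(strategyA)
  z <- data.frame(siteA = seq_len(n), siteB = n + seq_len(n),
                  strategyA = as.integer(strategyA),
                  strategyB = as.integer(strategyB),
                  cloneA = seq_len(n),
                  cloneB = ifelse(rep_len(intraclonal, n), seq_len(n),
                                  n + seq_len(n)),
                  intraclonal = rep_len(intraclonal, n))
  side <- ceiling(sqrt(2 * n))
  new("MatingOutcome", zygotes = z, mated = matrix(0L, side, side),
      nOccupied = as.integer(2 * n))
}

# Independent oracle: maximum bipartite matching size between opposite
# mating types under Moore adjacency, by augmenting paths (small grids only).
maxMatchingMoore <- function(lattice) {
  mt <- lattice@matingType
  L <- nrow(mt)
  torus <- lattice@boundary == "torus"
  idxP <- which(mt == 1L)
  idxM <- which(mt == 2L)
  if (!length(idxP) || !length(idxM)) return(0L)
  adj <- lapply(idxP, function(i) {
    r <- (i - 1) %% L + 1
    c <- (i - 1) %/% L + 1
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (torus) {
        rr <- (rr - 1) %% L + 1; cc <- (cc - 1) %% L + 1
      } else if (rr < 1 || rr > L || cc < 1 || cc > L) next
      j <- (cc - 1) * L + rr
      if (mt[j] == 2L) nb <- c(nb, match(j, idxM))
    }
    nb
  })
  matchM <- rep(0L, length(idxM))
  tryAugment <- function(u, seen) {
    for (v in adj[[u]]) {
      if (seen[v]) next
      seen[v] <- TRUE
      if (matchM[v] == 0L) {
        matchM[v] <<- u
        return(list(ok = TRUE, seen = seen))
      }
      res <- tryAugment(matchM[v], seen)
      seen <- res$seen
      if (res$ok) {
        matchM[v] <<- u
        return(list(ok = TRUE, seen = seen))
      }
    }
    list(ok = FALSE, seen = seen)
  }
  size <- 0L
  for (u in seq_along(idxP)) {
    if (tryAugment(u, rep(FALSE, length(idxM)))$ok) size <- size + 1L
  }
  size
}
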