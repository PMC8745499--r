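# Independent brute-force oracles, shared by the unit and acceptance suites.
# These deliberately use naive per-definition logic, not the package's code
# paths.

# longest ATG..stop ORF by scanning every start position
oracleLongestOrf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  for (i in seq_len(max(0L, n - 5L))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

oracleRevcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(seq)), "")[[1]]),
        collapse = "")
}

# class code per the written definitions, plain integer arithmetic
oracleClassCode <- function(cs, ce, cstrand, refs) {
  span <- c(min(cs), max(ce))
  ovl <- function(a1, a2, b1, b2) a1 <= b2 && a2 >= b1
  exonOvl <- function(as_, ae_, bs_, be_) {
    for (x in seq_along(as_)) for (y in seq_along(bs_))
      if (ovl(as_[x], ae_[x], bs_[y], be_[y])) return(TRUE)
    FALSE
  }
  anySpan <- FALSE; sameEx <- list(); oppEx <- FALSE; inIntron <- FALSE
  for (r in refs) {
    rs <- sort(r$starts); re <- sort(r$ends)
    if (!ovl(span[1], span[2], rs[1], re[length(re)])) next
    anySpan <- TRUE
    if (r$strand == cstrand && length(rs) == length(cs) &&
        all(rs == sort(cs)) && all(re == sort(ce))) return("=")
    if (length(rs) > 1) {
      for (j in seq_len(length(rs) - 1))
        if (re[j] + 1 <= span[1] && rs[j + 1] - 1 >= span[2]) inIntron <- TRUE
    }
    if (exonOvl(cs, ce, rs, re)) {
      if (r$strand == cstrand) sameEx <- c(sameEx, list(r)) else oppEx <- TRUE
    }
  }
  if (inIntron) return("i")
  if (oppEx) return("x")
  if (length(sameEx)) {
    if (length(cs) == 1) {
      for (r in sameEx) {
        rs <- sort(r$starts); re <- sort(r$ends)
        if (length(rs) < 2) next
        for (j in seq_len(length(rs) - 1))
          if (ovl(cs, ce, re[j] + 1, rs[j + 1] - 1)) return("e")
      }
    }
    return("o")
  }
  if (!anySpan) return("u")
  "other"
}

# all-pairs quadratic scan for cis pairs: gap between spans strictly < window
oracleCisPairs <- function(spans, lncIds, geneIds, window) {
  out <- list()
  for (l in lncIds) for (g in geneIds) {
    a <- spans[[l]]; b <- spans[[g]]
    d <- if (a[1] <= b[2] && a[2] >= b[1]) 0L
         else if (a[2] < b[1]) b[1] - a[2] - 1L else a[1] - b[2] - 1L
    if (d < window) out[[length(out) + 1]] <-
        data.frame(lncrna_id = l, gene_id = g, distance_bp = d)
  }
  if (!length(out)) return(data.frame(lncrna_id = character(),
                                      gene_id = character(),
                                      distance_bp = integer()))
  do.call(rbind, out)
}

# independent R implementation of the local hybridization DP
oracleHybridize <- function(lnc, mrna, gap = 4) {
  ps <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) 3
    else if (p %in% c("AT", "TA")) 2
    else if (p %in% c("GT", "TG")) 1
    else -4
  }
  l <- strsplit(chartr("U", "T", toupper(lnc)), "")[[1]]
  m <- rev(strsplit(chartr("U", "T", toupper(mrna)), "")[[1]])
  H <- matrix(0, length(l) + 1, length(m) + 1)
  best <- 0
  for (i in seq_along(l)) for (j in seq_along(m)) {
    H[i + 1, j + 1] <- max(0, H[i, j] + ps(l[i], m[j]),
                           H[i, j + 1] - gap, H[i + 1, j] - gap)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# exhaustive check at tiny sizes: best global alignment (independent NW)
# over every substring pair equals the local DP optimum
oracleHybridizeExhaustive <- function(lnc, mrna, gap = 4) {
  ps <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) 3
    else if (p %in% c("AT", "TA")) 2
    else if (p %in% c("GT", "TG")) 1
    else -4
  }
  l <- strsplit(toupper(lnc), "")[[1]]
  m <- rev(strsplit(toupper(mrna), "")[[1]])
  nw <- function(a, b) {
    F <- matrix(0, length(a) + 1, length(b) + 1)
    F[, 1] <- -gap * (0:length(a))
    F[1, ] <- -gap * (0:length(b))
    for (i in seq_along(a)) for (j in seq_along(b))
      F[i + 1, j + 1] <- max(F[i, j] + ps(a[i], b[j]),
                             F[i, j + 1] - gap, F[i + 1, j] - gap)
    F[length(a) + 1, length(b) + 1]
  }
  best <- 0
  for (i1 in seq_along(l)) for (i2 in i1:length(l))
    for (j1 in seq_along(m)) for (j2 in j1:length(m))
      best <- max(best, nw(l[i1:i2], m[j1:j2]))
  best
}

# exact hypergeometric upper tail by enumeration
oracleHyperTail <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
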