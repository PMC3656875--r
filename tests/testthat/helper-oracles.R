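# Independent oracles, deliberately sharing no code with the package.

# brute-force IUPAC site scan: check every position character by character
brute_sites <- function(seq, recognition) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  rc <- strsplit(recognition, "")[[1]]
  L <- length(rc)
  chars <- strsplit(seq, "")[[1]]
  n <- nchar(seq)
  hits <- integer(0)
  if (n < L) return(hits)
  for (i in seq_len(n - L + 1)) {
    okpos <- TRUE
    for (j in seq_len(L)) {
      if (!chars[i + j - 1] %in% sets[[rc[j]]]) { okpos <- FALSE; break }
    }
    if (okpos) hits <- c(hits, i - 1L)
  }
  hits
}

# Weir & Cockerham (1984) theta from a genotype matrix (sites x ind)
wc_fst <- function(geno, pops) {
  f <- factor(pops)
  r <- nlevels(f)
  suma <- sumabc <- 0
  for (s in seq_len(nrow(geno))) {
    g <- geno[s, ]
    ok <- !is.na(g)
    ni <- tapply(ok, f, sum)
    if (any(ni == 0)) next
    pi <- tapply(g[ok], f[ok], sum) / (2 * ni)
    hi <- tapply(g[ok] == 1, f[ok], mean)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    if (nbar <= 1) next
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    suma <- suma + a
    sumabc <- sumabc + a + b + cc
  }
  suma / sumabc
}

# does an unrooted tree contain a split separating `tips` from the rest?
has_split <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  want <- sort(match(tips, labs))
  rest <- sort(setdiff(seq_along(labs), want))
  for (cl in pp) {
    s <- sort(cl)
    if (identical(s, want) || identical(s, rest)) return(TRUE)
  }
  FALSE
}
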