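# Independent oracles used by the tests. These deliberately re-derive
# results through different code paths than the package implementation.

# plain Needleman-Wunsch with linear gap penalty; returns the two aligned
# strings (ties resolved diagonal > up > left)
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(
        S[i, j] + if (A[i] == B[j]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap
      )
    }
  }
  ra <- rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1
    }
  }
  c(paste(ra, collapse = ""), paste(rb, collapse = ""))
}

# independent nearest-neighbor Tm evaluation (SantaLucia 1998 unified set,
# table typed out in full rather than folded by complement symmetry)
oracle_nn_tm <- function(s, conc_nM = 500, na_mM = 50) {
  dH_tab <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
              CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
              GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
              TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  dS_tab <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
              CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
              GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
              TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  steps <- paste0(ch[-n], ch[-1])
  dH <- sum(dH_tab[steps])
  dS <- sum(dS_tab[steps])
  ends <- ch[c(1, n)]
  dH <- dH + sum(ifelse(ends %in% c("G", "C"), 0.1, 2.3))
  dS <- dS + sum(ifelse(ends %in% c("G", "C"), -2.8, 4.1))
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

# brute-force check over the three unrooted quartet topologies: which split
# minimizes the four-point sum for an additive matrix
oracle_quartet_split <- function(d) {
  stopifnot(nrow(d) == 4)
  ids <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sums <- vapply(splits, function(s) {
    o <- setdiff(1:4, s)
    d[s[1], s[2]] + d[o[1], o[2]]
  }, numeric(1))
  ids[splits[[which.min(sums)]]]
}

# random sequence tibble
random_seqs <- function(n, len, seed = 1, ids = sprintf("s%02d", seq_len(n))) {
  withr::with_seed(seed, tibble::tibble(
    id = ids,
    seq = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
  ))
}

angelica_panel <- function() {
  read_primer_panel(system.file("extdata", "angelica_panel.tsv",
                                package = "scarmux"))
}
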