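# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), duplex of a strand with its perfect
# complement.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)   # per G/C terminal
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)    # per A/T terminal

#' Primer melting temperature
#'
#' Short oligos (<= 14 nt) use the Wallace rule `2(A+T) + 4(G+C)`. Longer
#' primers use the SantaLucia (1998) unified nearest-neighbor model:
#' `Tm = 1000 * dH / (dS + R * log(conc/4)) - 273.15`, with the salt
#' correction `dS += 0.368 * (n - 1) * log([Na+])`.
#'
#' @param x Character vector of unambiguous primer sequences, length >= 4.
#' @param conc_nM Total oligo concentration in nM (nearest-neighbor regime).
#' @param na_mM Monovalent cation concentration in mM.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature(c("AAAA", "GGGG", "ATCGGCGTCTTTCCAAAATGC"))
#' @export
melting_temperature <- function(x, conc_nM = 500, na_mM = 50) {
  x <- toupper(x)
  if (any(nchar(x) < 4)) {
    scar_abort("melting temperature needs primers of length >= 4",
               class = "scar_format")
  }
  if (any(grepl("[^ACGT]", x))) {
    scar_abort("ambiguity codes are not supported in melting_temperature()",
               class = "scar_unsupported_input")
  }
  vapply(x, function(s) {
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    gc <- sum(ch %in% c("G", "C"))
    if (n <= 14) {
      return(2 * (n - gc) + 4 * gc)
    }
    nn <- paste0(ch[-n], ch[-1])
    dH <- sum(NN_DH[nn])
    dS <- sum(NN_DS[nn])
    for (term in ch[c(1, n)]) {
      init <- if (term %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
      dH <- dH + init[["dH"]]
      dS <- dS + init[["dS"]]
    }
    dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
    R <- 1.987
    1000 * dH / (dS + R * log(conc_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  vapply(strsplit(toupper(x), "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")) / length(ch), numeric(1))
}
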