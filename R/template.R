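#' Synthetic template for a single primer pair
#'
#' Concatenates the forward primer, a seeded random spacer and the reverse
#' complement of the reverse primer, so the pair amplifies a product of
#' exactly `nchar(forward) + spacer_len + nchar(reverse)` bp. The spacer is
#' re-drawn (deterministically) if it spuriously creates any additional
#' zero-mismatch binding site for the screened primers.
#'
#' @param forward,reverse Primer sequences 5'->3' (reverse as synthesized).
#' @param spacer_len Spacer length in nt.
#' @param seed Seed for the spacer draw.
#' @param screen Optional `scar_panel` whose every primer is screened
#'   against spurious sites; defaults to just the given pair.
#' @return The template sequence string.
#' @export
pair_template <- function(forward, reverse, spacer_len = 215, seed = 1,
                          screen = NULL) {
  primers <- if (is.null(screen)) c(forward, reverse) else
    c(screen$forward, screen$reverse)
  params <- pcr_params(max_mismatch = 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (attempt in 1:100) {
    spacer <- paste(sample(SCAR_BASES, spacer_len, replace = TRUE), collapse = "")
    tpl <- paste0(forward, spacer, dna_revcomp(reverse))
    n_sites <- sum(vapply(primers, function(p)
      nrow(find_binding_sites(tpl, p, params)), integer(1)))
    if (n_sites == 2) return(tpl)   # exactly the two intended sites
  }
  scar_abort("could not draw a spacer free of spurious primer sites",
             class = "scar_config")
}
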