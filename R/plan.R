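#' Screen-design planning arithmetic
#'
#' Translates a pool size, per-hairpin representation and multiplicity of
#' infection into the cell, DNA and PCR numbers a barcode-recovery protocol
#' needs: `infected_cells = n_shrna x representation` cells must be
#' PCR-amplified; `maintained_cells = infected_cells / moi` cells must be
#' kept in culture; at roughly 6 pg genomic DNA per diploid human cell the
#' amplified DNA mass is `infected_cells x 6 pg`, split into parallel PCR
#' reactions of `ug_per_pcr` (default 2) micrograms each.
#'
#' @param n_shrna Number of distinct hairpins in the pool.
#' @param representation Average infected cells per hairpin (default 1000).
#' @param moi Multiplicity of infection in (0, 1]; values above 1 would mean
#'   multiple integrations per cell, which this planner does not model.
#' @param pg_per_cell Genomic DNA per cell in picograms (default 6).
#' @param ug_per_pcr DNA input per PCR reaction in micrograms (default 2).
#' @return One-row tibble: `n_shrna`, `representation`, `moi`,
#'   `infected_cells`, `maintained_cells`, `dna_mass_ug`, `n_pcr`.
#' @export
plan_screen <- function(n_shrna, representation = 1000, moi = 0.7,
                        pg_per_cell = 6, ug_per_pcr = 2) {
  if (any(c(n_shrna, representation, moi, pg_per_cell, ug_per_pcr) <= 0))
    abort("all planning inputs must be positive")
  if (moi > 1)
    abort("moi must be <= 1 (multi-integration planning unsupported)")
  infected <- n_shrna * representation
  dna_ug <- infected * pg_per_cell * 1e-6
  tibble(
    n_shrna = n_shrna, representation = representation, moi = moi,
    infected_cells = infected,
    maintained_cells = infected / moi,
    dna_mass_ug = dna_ug,
    n_pcr = ceiling(dna_ug / ug_per_pcr)
  )
}
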