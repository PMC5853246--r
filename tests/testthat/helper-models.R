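# shared model fixtures, built in code

# full dominance series incl. the SCA6-type allele
default_model <- function(...) si_model(cacao_s_alleles(), ...)

# chromosome-1 alleles as seen through mSI_103 sizes: the Amelonado 223,
# SCA6 225 (activator of elimination of 223/223) and Criollo 228 (not an
# activator)
ch1_alleles <- function()
  si_alleles(c("Am223", "Sca225", "Cri228"),
             c("active", "active", "active"), c(2L, 1L, 2L))

ch1_model <- function(...)
  si_model(ch1_alleles(),
           ch1_pairs = data.frame(activator = "Sca225", target = "Am223"),
           gametic_locus = NA, ...)

br59_cross <- function(n = 109L, baseline_abortion = 0.10)
  cross_spec(mother = list(CH1 = c("Am223", "Sca225")), n_offspring = n,
             baseline_abortion = baseline_abortion)

uf676_ics95_cross <- function(n = 87L)
  cross_spec(mother = list(CH1 = c("Am223", "Cri228")), n_offspring = n)

# TSH516-type selfing at the gametic locus: amorphous Sf x active SCA6
tsh516_cross <- function(n = 877L, baseline_abortion = 0.10)
  cross_spec(mother = list(CH4 = c("Sf", "S_sca")), n_offspring = n,
             baseline_abortion = baseline_abortion)

f2_fixture_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- counts_to_marker_table(f2_segregation_counts())
    cache
  }
})

# tiny SSR + phenotype tables for screen unit tests
toy_screen_data <- function() {
  ssr <- data.frame(
    individual = paste0("i", 1:12),
    m1 = c("100/100", "100/100", "100/102", "100/102", "100/102", "102/102",
           "102/102", "102/102", "100/100", "100/102", "102/102", "100/100"),
    m2 = c("200/204", "200/204", "200/200", "204/204", "200/204", "200/200",
           "204/204", "200/204", "200/200", "204/204", "200/200", "200/204"),
    stringsAsFactors = FALSE)
  phen <- data.frame(individual = paste0("i", 1:12),
                     sc_status = c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0, 0, 1),
                     stringsAsFactors = FALSE)
  list(ssr = ssr, phen = phen)
}
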