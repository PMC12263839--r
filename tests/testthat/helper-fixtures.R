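# Shared fixtures, built in code at test time.

# A small synthetic reference and its site table (fixed seed).
test_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- generate_reference(40, 80, seed = 20240101)
    ref
  }
})

test_site_table <- function() test_reference()$site_table

# Hand-specified two-gene site table for worked examples.
toy_site_table <- function() {
  pg <- data.frame(gene = c("A", "B"), nN = c(600, 600), nS = c(200, 200),
                   length_nt = c(800, 800), stringsAsFactors = FALSE,
                   row.names = c("A", "B"))
  st <- list(per_gene = pg,
             totals = list(nN_total = 1200, nS_total = 400,
                           length_total = 1600),
             skipped = character(0))
  class(st) <- "site_table"
  st
}

# Minimal mutation-record constructor.
make_mutations <- function(gene, class, af = NA_real_, sample = "S1",
                           patient = "P1", position = NULL) {
  n <- length(gene)
  out <- data.frame(
    patient_id = rep_len(patient, n), sample_id = rep_len(sample, n),
    gene = gene,
    variant_class = factor(class, levels = c("nonsilent", "silent", "other")),
    allele_frequency = rep_len(af, n),
    raw_class = as.character(class), stringsAsFactors = FALSE)
  if (!is.null(position)) out$position <- position
  out
}

# Paired cohort at the profile level (no estimation noise): x from the
# log-uniform omega law, y contracted toward 1 by kappa plus Gaussian noise.
make_profile_pairs <- function(n, kappa, noise_sd) {
  x <- exp(stats::runif(n, log(0.3), log(3)))
  y <- 1 + kappa * (x - 1) + stats::rnorm(n, 0, noise_sd)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             dnds_1 = x, dnds_2 = y, dis = abs(1 - y), delta = y - x,
             stringsAsFactors = FALSE)
}
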