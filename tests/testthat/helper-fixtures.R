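# Shared fixtures: toy haplotype matrices, small locus specs, a cached
# desk-scale reference table, and the independent coalescent oracle.

toy_hm <- function(mat, pops, L = 100, locus = "toy") {
  mat <- as.matrix(mat)
  haplotype_matrix(mat, pops,
                   positions = seq_len(ncol(mat)) / (ncol(mat) + 1),
                   locus = locus, length = L, check = FALSE)
}

one_pop_locus <- function(n, L = 1000, scaling = 1, mu = 1e-6) {
  locus_spec("L1", L, c(murphyi = n, plumbeus = 0, matannensis = 0),
             inheritance_scaling = scaling, mu_range = c(mu, mu))
}

# a draw that effectively collapses to a single constant-size population
one_pop_draw <- function(N) {
  d <- draw_parameters(demographic_model("Is"), 1)
  d$ne_murphyi <- N
  d$t_root <- 5.9e6
  d$t_pt <- 1.1e6
  d
}

# small 3-locus structure for fast multi-population dataset simulations
tiny_specs <- function() {
  list(cytb = locus_spec("cytb", 600,
                         c(murphyi = 10, plumbeus = 6, matannensis = 4),
                         0.25, c(1e-8, 1e-8)),
       nuc1 = locus_spec("nuc1", 800,
                         c(murphyi = 8, plumbeus = 6, matannensis = 4),
                         1, c(5e-10, 1.5e-9)),
       nuc2 = locus_spec("nuc2", 500,
                         c(murphyi = 6, plumbeus = 4, matannensis = 4),
                         1, c(5e-10, 1.5e-9)))
}

write_fasta_lines <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Desk-scale reference table shared by the heavy acceptance tests; built
# once per test run.
.pd_cache <- new.env(parent = emptyenv())

acceptance_ref_table <- function(nsims = 5000) {
  key <- paste0("ref_", nsims)
  if (is.null(.pd_cache[[key]])) {
    set.seed(20240312)
    .pd_cache[[key]] <- simulate_reference_table(
      pd_model_ids(), nsims, default_locus_specs())
  }
  .pd_cache[[key]]
}

# Independent coalescent oracle: segregating-site counts from msprime for a
# two-population split model (diploid sizes, infinite-sites mutation).
msprime_S <- function(n_dip1, n_dip2, N, t_split, mu, L, reps, seed) {
  script <- sprintf(paste0(
    "import msprime\n",
    "dem = msprime.Demography()\n",
    "dem.add_population(name='A', initial_size=%g)\n",
    "dem.add_population(name='B', initial_size=%g)\n",
    "dem.add_population(name='C', initial_size=%g)\n",
    "dem.add_population_split(time=%g, derived=['A','B'], ancestral='C')\n",
    "out = []\n",
    "for ts in msprime.sim_ancestry(samples={'A': %d, 'B': %d},\n",
    "        demography=dem, sequence_length=%g, ploidy=2,\n",
    "        num_replicates=%d, random_seed=%d):\n",
    "    mts = msprime.sim_mutations(ts, rate=%g, discrete_genome=False)\n",
    "    out.append(mts.num_sites)\n",
    "print(' '.join(map(str, out)))\n"),
    N, N, N, t_split, n_dip1, n_dip2, L, reps, seed, mu)
  out <- suppressWarnings(
    system2("python", "-", input = script, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("msprime oracle failed: ", paste(out, collapse = "\n"))
  scan(text = out[length(out)], quiet = TRUE)
}
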