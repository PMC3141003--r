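# Shared fixtures. The two full-scale experiments (planted and null) are
# expensive (print-tip normalization over 22 arrays), so they are built
# lazily once per test run and reused by the state-profiling, diffexpr and
# acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The stated world of the recovery criterion: 2,000 probes (1,715 cnidarian
# plus symbiont/prokaryote controls), 5 + 6 specimens in dye-swap pairs
# against a common reference, planted effect 1.5 log2, activity 0.9,
# noise 0.3, fixed seed.
planted_state_experiment <- function() {
  cached("planted_state", function() {
    ann <- generate_annotation(1715, 200, 85, go_terms_per_gene = 2,
                               seed = 7)
    cfg <- state_sim_config(n_probes = 2000, n_planted_sy = 60,
                            n_planted_apo = 80, effect_log2 = 1.5,
                            activity_prob = 0.9, noise_sd = 0.3, seed = 7)
    sim <- generate_state_experiment(cfg, ann)
    host <- ann$probe_id[ann$origin == "cnidarian"]
    ma <- normalize_between_arrays(
      normalize_within_array(compute_ma(background_correct(sim$scans)),
                             fit_probes = host),
      method = "aquantile")
    contrasts <- suppressWarnings(run_state_contrasts(ma, sim$specimens))
    list(ann = ann, cfg = cfg, sim = sim, ma = ma, contrasts = contrasts)
  })
}

# Null counterpart: same geometry, no planted effects, all-cnidarian
# annotation (symbiont probes are genuinely state-dependent, so a type-I
# check must not count them).
null_state_experiment <- function() {
  cached("null_state", function() {
    ann <- generate_annotation(2000, 0, 0, go_terms_per_gene = 2, seed = 11)
    cfg <- state_sim_config(n_probes = 2000, n_planted_sy = 0,
                            n_planted_apo = 0, noise_sd = 0.3, seed = 11)
    sim <- generate_state_experiment(cfg, ann)
    ma <- normalize_between_arrays(
      normalize_within_array(compute_ma(background_correct(sim$scans))),
      method = "aquantile")
    contrasts <- suppressWarnings(run_state_contrasts(ma, sim$specimens))
    list(ann = ann, cfg = cfg, sim = sim, ma = ma, contrasts = contrasts)
  })
}

# Small noiseless state experiment (closure checks).
noiseless_state_experiment <- function(activity_prob = 1, seed = 5,
                                       n_probes = 300) {
  ann <- generate_annotation(round(n_probes * 0.85), round(n_probes * 0.1),
                             n_probes - round(n_probes * 0.85) -
                               round(n_probes * 0.1),
                             go_terms_per_gene = 2, seed = seed)
  cfg <- state_sim_config(n_probes = n_probes, n_planted_sy = 15,
                          n_planted_apo = 20, effect_log2 = 1.5,
                          activity_prob = activity_prob, noise_sd = 0,
                          dye_bias_amplitude = 0, bg_mean = 0, seed = seed)
  sim <- generate_state_experiment(cfg, ann)
  ma <- compute_ma(background_correct(sim$scans, offset = 0))
  list(ann = ann, cfg = cfg, sim = sim, ma = ma)
}

# A minimal hand-built scan pair for IO/preprocess unit tests.
toy_scan_set <- function() {
  scan <- function(fg_r, fg_g, bg = 10) {
    data.frame(probe_id = sprintf("p%02d", seq_along(fg_r)),
               print_tip_group = 1L,
               fg_red = fg_r, bg_red = bg, fg_green = fg_g, bg_green = bg,
               stringsAsFactors = FALSE)
  }
  scans <- list(a1 = scan(c(2010, 1010, 510), c(1010, 1010, 1010)),
                a2 = scan(c(1010, 1010, 1010), c(2010, 1010, 510)))
  design <- data.frame(array_id = c("a1", "a2"),
                       cy3_sample = c("REF", "S1"),
                       cy5_sample = c("S1", "REF"),
                       dye_swap_of = c(NA, "a1"),
                       stringsAsFactors = FALSE)
  structure(list(scans = scans, design = design), class = "array_scan_set")
}

expect_tsv_identical <- function(path1, path2) {
  expect_identical(readLines(path1), readLines(path2))
}
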