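# Shared helpers: random valid rating sheets and an independent brute-force
# scoring oracle built straight from the published point table, kept separate
# from the package's lookup path.

oracle_points <- list(
  hilar_enlarged   = c(0, 1, 2, 3),
  hilar_density    = c(0, 2, 4, 6),
  hilar_blurred    = c(0, 3, 6, 9),
  kerley_b         = c(0, 4, 8),
  micronoduli      = c(0, 4, 8),
  fissure_widening = c(0, 4, 8, 12),
  cuffs            = c(0, 4, 8, 12),
  perihilar_haze   = c(0, 5, 10, 15),
  diffuse_density  = c(0, 5, 10, 15)
)

oracle_total <- function(levels) {
  sum(vapply(names(levels),
             function(id) oracle_points[[id]][levels[[id]] + 1L],
             numeric(1)))
}

random_sheet <- function() {
  vapply(oracle_points, function(p) sample.int(length(p), 1) - 1L, integer(1))
}

random_call_matrix <- function(n_readers, case_ids, p_edema = 0.5) {
  m <- matrix(sample(c("edema", "no_edema"), n_readers * length(case_ids),
                     replace = TRUE, prob = c(p_edema, 1 - p_edema)),
              n_readers, length(case_ids),
              dimnames = list(sprintf("r%d", seq_len(n_readers)), case_ids))
  m
}

# balanced reference: first half edema, second half no_edema
balanced_reference <- function(n_cases) {
  stopifnot(n_cases %% 2 == 0)
  reference_standard(data.frame(
    case_id = sprintf("c%03d", seq_len(n_cases)),
    evlw = rep(c(18, 6), each = n_cases / 2)))
}
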