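# Small builders and transcribed worked-example values from a published
# AD-vs-control diffusion-kurtosis network study, used for identity and
# hub-rule checks.

tg_edges <- function(edges, n, weights = NULL) {
  thresholded_graph(matrix(edges, ncol = 2, byrow = TRUE),
                    weights = weights, n_nodes = n)
}

# Reported small-world table cells: gamma and lambda columns plus the sigma
# the study prints for them (sigma is defined as gamma/lambda).
ref_sigma_cells <- data.frame(
  metric = c("MK", "RK", "MD", "AK", "FN"),
  group  = c("AD", "AD", "AD", "NC", "NC"),
  gamma  = c(2.16, 1.75, 1.67, 1.79, 2.06),
  lambda = c(1.06, 1.06, 1.11, 1.04, 1.12),
  sigma  = c(2.04, 1.65, 1.50, 1.72, 1.84),
  stringsAsFactors = FALSE
)

# Normalised-betweenness hub tables (control and patient group) as printed:
# region, cortex class, bi, in descending bi order.
ref_hub_control <- data.frame(
  region = c("Left inferior frontal gyrus, opercular part", "Right precuneus",
             "Left hippocampus", "Right inferior frontal gyrus, opercular part",
             "Left superior frontal gyrus, orbital part", "Left fusiform gyrus",
             "Left superior temporal gyrus", "Right fusiform gyrus",
             "Left thalamus", "Right inferior frontal gyrus, triangular part"),
  class = c("Paralimbic", "Paralimbic", "Paralimbic", "Paralimbic",
            "Paralimbic", "Association", "Association", "Association",
            "Paralimbic", "Association"),
  bi = c(4.69, 4.40, 4.26, 4.05, 3.40, 3.30, 2.79, 2.67, 2.24, 2.20),
  stringsAsFactors = FALSE
)

ref_hub_patient <- data.frame(
  region = c("Right superior temporal gyrus", "Right inferior temporal gyrus",
             "Right middle temporal gyrus", "Left middle temporal gyrus",
             "Right temporal pole, superior temporal gyrus", "Left insula",
             "Left heschl gyrus", "Right fusiform gyrus",
             "Left inferior parietal gyrus", "Left middle frontal gyrus"),
  class = c("Association", "Association", "Association", "Association",
            "Paralimbic", "Association", "Association", "Association",
            "Association", "Association"),
  bi = c(6.87, 3.96, 3.62, 3.52, 3.44, 3.19, 3.04, 2.86, 2.64, 2.55),
  stringsAsFactors = FALSE
)

# A small cohort config used across tests: fast to generate, default
# study-condition effects.
test_cohort <- function(seed = 1, metrics = "MK", ...) {
  cohort_config(seed = seed, metrics = metrics, ...)
}
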