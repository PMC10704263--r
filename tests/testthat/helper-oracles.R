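# Independent oracles and fixture builders shared across the suite.

# Random physical Mueller matrix as a product of textbook factors:
# depolarizer . retarder . diattenuator (optionally times a rotator and an
# intensity scale). Physical by construction.
random_physical_mueller <- function(scale = FALSE) {
  m <- mm_depolarizer(runif(1, 0, 0.8)) %*%
    mm_retarder(runif(1, 0, pi), runif(1, 0, 180)) %*%
    mm_diattenuator(runif(1, 0, 0.8), runif(1, 0, 180))
  if (scale) m <- runif(1, 0.2, 5) * m
  m
}

# O(n^2) concordant-pair AUROC oracle (ties get half credit).
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

# Naive per-element sort-and-middle median of a (4, 4, H, W) block.
median_mueller_naive <- function(mm_image) {
  out <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    v <- as.vector(mm_image[i, j, , ])
    v <- sort(v)
    n <- length(v)
    out[i, j] <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  }
  out
}

# Small feature cohort with a planted linear signal in chosen features;
# returns a tibble shaped like generate_cohort()$features.
make_feature_cohort <- function(n_patients_per_class = 10, rois_per_patient = 6,
                                informative = c("delta_L", "D"),
                                gap = 2, noise_sd = 1, seed = 1) {
  set.seed(seed)
  feats <- mm_feature_names()
  rows <- list()
  idx <- 0
  for (cls in 0:1) {
    for (p in seq_len(n_patients_per_class)) {
      pid <- sprintf("C%dP%02d", cls, p)
      for (r in seq_len(rois_per_patient)) {
        idx <- idx + 1
        x <- rnorm(length(feats), 0, noise_sd)
        names(x) <- feats
        x[informative] <- x[informative] + cls * gap
        rows[[idx]] <- tibble::tibble(
          roi_id = sprintf("R%04d", idx), patient_id = pid,
          label = cls, !!!as.list(x)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Class parameter pair used by the pipeline-level tests: the entire class
# contrast sits in linear retardance (gap of ~9 patient-level sds), while
# diattenuation and depolarization are identically distributed in both
# classes. The separation signal therefore spans the whole redundant
# retardance-driven feature family (delta_L, R, central elements, b, t1)
# and no single weakly-informative feature can carry a spurious split.
separated_params <- function() {
  list(
    nolr = tissue_class_params(1.3, 0.10, 0.30,
                               delta_sd = c(0.10, 0.08, 0.04)),
    lr = tissue_class_params(0.4, 0.10, 0.30,
                             delta_sd = c(0.10, 0.08, 0.04))
  )
}
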