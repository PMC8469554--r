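# shared fixtures, all generated in code

default_truth <- function() flux_params(10, 1, 2)

# a small recovery dataset for one drug with a known single-mode truth
make_recovery <- function(mode = "deg-", cv = 0.1, seed = 1, drug = "EPI") {
  spec <- generation_spec(
    hypothesis = mode_hypothesis(stats::setNames(mode, drug)),
    panel = recovery_panel(drug), cv = cv, seed = seed)
  generate_timecourses(spec)
}

# random positive rate parameters spanning a few decades
random_params <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, flux_params(10^runif(1, -1, 2), 10^runif(1, -1, 1),
                           10^runif(1, -1, 1)),
            simplify = FALSE)
}

# greedy nearest-neighbour matching of detections to ground-truth spots
match_spots <- function(det, truth, max_dist = 4) {
  used <- rep(FALSE, nrow(truth))
  klass_hat <- rep(NA_character_, nrow(truth))
  n_unmatched_det <- 0
  for (i in seq_len(nrow(det))) {
    if (nrow(truth) == 0) { n_unmatched_det <- n_unmatched_det + 1; next }
    d <- sqrt((truth$x - 1 - det$x[i])^2 + (truth$y - 1 - det$y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= max_dist) {
      used[j] <- TRUE
      klass_hat[j] <- det$klass[i]
    } else {
      n_unmatched_det <- n_unmatched_det + 1
    }
  }
  list(truth_class = truth$klass, pred_class = klass_hat,
       n_false_pos = n_unmatched_det)
}

f1_score <- function(truth_class, pred_class, positive) {
  tp <- sum(truth_class == positive & !is.na(pred_class) &
              pred_class == positive)
  fp <- sum(truth_class != positive & !is.na(pred_class) &
              pred_class == positive)
  fn <- sum(truth_class == positive &
              (is.na(pred_class) | pred_class != positive))
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
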