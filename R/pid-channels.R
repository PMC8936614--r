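#' Channel-wise partial information decomposition
#'
#' For every EEG channel, decomposes the information that the two
#' unisensory encoding-model predictions carry about the multisensory
#' model's prediction. The V and H encoders are trained on their own
#' conditions; the VH-condition trials are split into `folds` folds and the
#' VH encoder is re-trained on the other folds so that each held-out VH
#' trial receives out-of-fold target predictions. Concatenated held-out
#' predictions form each channel's triplet, decomposed with [pid_ccs()].
#'
#' @param trials_vh,trials_v,trials_h Trial lists (with `eeg`, `velocity`)
#'   for the three conditions.
#' @param spec A [lag_spec()].
#' @param lambda Ridge penalty for the encoders.
#' @param folds Cross-validation folds over VH trials.
#' @param seed Seed for the fold assignment.
#' @param estimator Redundancy estimator, `"ccs"` or `"mmi"`.
#' @return A `pid_result`: data frame `atoms` (per channel: red, uniq_v,
#'   uniq_h, syn, MIs) plus the per-channel `triplets` (with trial ids)
#'   needed by [permutation_test()].
#' @export
channelwise_pid <- function(trials_vh, trials_v, trials_h, spec, lambda = 4,
                            folds = 5, seed = 1L,
                            estimator = c("ccs", "mmi")) {
  estimator <- match.arg(estimator)
  if (!length(trials_v) || !length(trials_h) || !length(trials_vh))
    stop("all three condition trial sets are required")
  enc_v <- fit_encoding(trials_v, spec, lambda)
  enc_h <- fit_encoding(trials_h, spec, lambda)
  nch <- ncol(as.matrix(trials_vh[[1]]$eeg))
  labels <- attr(trials_vh[[1]]$eeg, "labels") %||% paste0("ch", seq_len(nch))
  nt <- length(trials_vh)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), nt)))
  pred_t <- vector("list", nt)
  pred_v <- vector("list", nt)
  pred_h <- vector("list", nt)
  for (f in seq_len(folds)) {
    train <- which(fold_of != f)
    test <- which(fold_of == f)
    if (!length(train) || !length(test)) next
    enc_vh <- fit_encoding(trials_vh[train], spec, lambda)
    for (i in test) {
      vel <- trials_vh[[i]]$velocity
      pred_t[[i]] <- predict_encoding(enc_vh, vel)
      pred_v[[i]] <- predict_encoding(enc_v, vel)
      pred_h[[i]] <- predict_encoding(enc_h, vel)
    }
  }
  used <- which(!vapply(pred_t, is.null, logical(1)))
  triplets <- lapply(seq_len(nch), function(ch) {
    list(channel = labels[ch],
         target = lapply(used, function(i) pred_t[[i]][, ch]),
         pred_v = unlist(lapply(used, function(i) pred_v[[i]][, ch])),
         pred_h = unlist(lapply(used, function(i) pred_h[[i]][, ch])),
         trial_len = vapply(used, function(i) nrow(pred_t[[i]]), 0L))
  })
  atoms <- do.call(rbind, lapply(triplets, function(tp) {
    res <- pid_ccs(unlist(tp$target), tp$pred_v, tp$pred_h,
                   estimator = estimator)
    data.frame(channel = tp$channel, red = res$red, uniq_v = res$uniq_v,
               uniq_h = res$uniq_h, syn = res$syn, mi_v = res$mi_v,
               mi_h = res$mi_h, mi_joint = res$mi_joint,
               co_info = res$co_info)
  }))
  structure(list(atoms = atoms, triplets = triplets, estimator = estimator,
                 folds = folds, seed = seed),
            class = "pid_result")
}

#' Permutation significance and FDR mask for PID atoms
#'
#' Shuffles the target signal at the whole-trial level (preserving
#' within-trial autocorrelation) `n_perm` times with the predictors fixed,
#' recomputes every atom per shuffle, and declares an observed atom
#' significant when it exceeds the `alpha_pct`-th percentile of its own
#' null; p-values use the plus-one rule
#' `p = (1 + #{null >= obs}) / (1 + n_perm)` and are Benjamini-Hochberg
#' corrected across channels per atom at rate `q`.
#'
#' @param result A `pid_result` from [channelwise_pid()].
#' @param n_perm Number of permutations (>= 100).
#' @param alpha_pct Percentile criterion (default 99).
#' @param q FDR rate (default 0.01).
#' @param seed Integer seed.
#' @return Data frame: channel, atom, observed bits, `p`, `exceeds_pct`,
#'   `significant` (exceeds percentile AND survives FDR).
#' @export
permutation_test <- function(result, n_perm = 1000, alpha_pct = 99,
                             q = 0.01, seed = 1L) {
  if (n_perm < 100) stop("need at least 100 permutations")
  tps <- result$triplets
  ntr <- length(tps[[1]]$target)
  if (ntr < 10) stop("fewer than 10 trials: permutation null is degenerate")
  atom_names <- c("red", "uniq_v", "uniq_h", "syn")
  nch <- length(tps)
  null_arr <- array(NA_real_, c(n_perm, nch, 4),
                    dimnames = list(NULL, NULL, atom_names))
  for (b in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, "perm", b), sample(ntr))
    for (ch in seq_len(nch)) {
      tp <- tps[[ch]]
      tgt <- permute_trial_blocks(tp$target, tp$trial_len, perm)
      res <- pid_ccs(tgt$target, tp$pred_v[tgt$keep], tp$pred_h[tgt$keep],
                     estimator = result$estimator)
      null_arr[b, ch, ] <- c(res$red, res$uniq_v, res$uniq_h, res$syn)
    }
  }
  out <- list()
  for (a in seq_along(atom_names)) {
    obs <- result$atoms[[atom_names[a]]]
    pvals <- numeric(nch); exceeds <- logical(nch)
    for (ch in seq_len(nch)) {
      nul <- null_arr[, ch, a]
      pvals[ch] <- (1 + sum(nul >= obs[ch])) / (1 + n_perm)
      exceeds[ch] <- obs[ch] > quantile(nul, alpha_pct / 100)
    }
    padj <- p.adjust(pvals, method = "BH")
    out[[a]] <- data.frame(channel = result$atoms$channel,
                           atom = atom_names[a], bits = obs, p = pvals,
                           p_fdr = padj, exceeds_pct = exceeds,
                           significant = exceeds & padj <= q)
  }
  do.call(rbind, out)
}

# reorder trial blocks of the target by `perm`; when trial lengths differ,
# each slot is truncated to the shorter of (original, permuted) trial so
# predictors stay sample-aligned
permute_trial_blocks <- function(target_list, lens, perm) {
  starts <- cumsum(c(0, lens[-length(lens)]))
  keep <- integer(0)
  out <- vector("list", length(perm))
  for (i in seq_along(perm)) {
    src <- target_list[[perm[i]]]
    m <- min(lens[i], length(src))
    out[[i]] <- src[seq_len(m)]
    keep <- c(keep, starts[i] + seq_len(m))
  }
  list(target = unlist(out), keep = keep)
}
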