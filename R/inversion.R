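#' Initial IPLS from RFD upshifts
#'
#' Crude starting landscape for the iterative inversion: per-bin RFD
#' increments, negatives clipped, smoothed with a 50 kb running window,
#' thresholded at the 80th percentile of the unmasked bins (the rest set to
#' zero) and normalised to unit sum.
#'
#' @param rfd a `profile` of kind `RFD`.
#' @param smooth_kb smoothing window, kb (default 50).
#' @param keep_quantile threshold quantile (default 0.8).
#' @return a `profile` of kind `IPLS`.
#' @export
init_ipls <- function(rfd, smooth_kb = 50, keep_quantile = 0.8) {
  stopifnot(inherits(rfd, "profile"))
  lat <- rfd$lattice
  inc <- profile_diff(rfd)
  inc$values <- pmax(inc$values, 0)
  if (all(is.na(inc$values) | inc$values <= 0))
    stop("no positive RFD increments: cannot initialise an IPLS from a flat or monotone-decreasing RFD profile")
  sm <- smooth_profile(inc, smooth_kb)
  v <- sm$values
  ok <- !lat$mask & !is.na(v)
  thr <- stats::quantile(v[ok], keep_quantile, names = FALSE)
  v[!ok] <- 0
  v[v <= thr] <- 0
  if (sum(v) <= 0) stop("thresholding removed all IPLS mass")
  profile(v, kind = "IPLS", lattice = lat)
}

# backward difference within chromosomes; first bin of each chromosome NA
profile_diff <- function(prof) {
  lat <- prof$lattice
  v <- prof$values
  out <- rep(NA_real_, lat$n_bins)
  off <- lattice_chrom_offsets(lat)
  for (ci in seq_along(lat$chrom_len_bins)) {
    n <- lat$chrom_len_bins[ci]
    idx <- seq.int(off[ci] + 1L, off[ci] + n)
    out[idx][-1L] <- diff(v[idx])
  }
  profile(out, kind = "generic", lattice = lat, normalize = FALSE)
}

# default chromosome split for the inverter: last chromosome held out for
# testing, the one before it for validation, the rest for training
default_split <- function(lattice) {
  nc <- length(lattice$chrom_names)
  if (nc < 3L)
    stop("need at least 3 chromosomes for a train/validation/test split; ",
         "supply `split` explicitly for smaller genomes")
  list(train = lattice$chrom_names[seq_len(nc - 2L)],
       val = lattice$chrom_names[nc - 1L],
       test = lattice$chrom_names[nc])
}

# per-chromosome network inputs: MRT fractions and 50 kb smoothed RFD,
# masked/missing set to 0
inverter_inputs <- function(pair, smooth_rfd_kb) {
  lat <- pair$lattice
  rfd_s <- smooth_profile(pair$rfd, smooth_rfd_kb)
  lapply(seq_along(lat$chrom_names), function(ci) {
    idx <- lattice_chrom_bins(lat, lat$chrom_names[ci])
    X <- cbind(mrt = pair$mrt$values[idx], rfd = rfd_s$values[idx])
    X[is.na(X)] <- 0
    X[pair$mask[idx], ] <- 0
    X
  })
}

#' Train the model inverter
#'
#' Trains the convolutional network to predict the effective initiation
#' landscape `(1 - r) * I + r * uniform` at the centre of a sliding
#' MRT + RFD window, from profiles simulated under that landscape. Targets
#' are scaled by their maximum over the training chromosomes to fit the
#' sigmoid output; the RFD input channel is smoothed at 50 kb; on-the-fly
#' augmentation re-assigns a random fraction of raw RFD bins to uniform
#' noise in \[-1, 1\] before smoothing, each epoch. Optimisation is
#' full-batch Adadelta on binary cross entropy with early stopping on the
#' validation chromosome.
#'
#' @param sim_pair a [profile_pair()] of simulated MRT and RFD.
#' @param target_ipls the structured IPLS `profile` the pair was simulated
#'   from.
#' @param r uniform initiation fraction used in the simulation.
#' @param seed RNG seed (weights, dropout, augmentation).
#' @param window_bins sliding-window width in bins (odd; default 401,
#'   i.e. 2005 kb at 5 kb).
#' @param n_filters,kernel convolution size (defaults 15 and 10).
#' @param epochs,patience early-stopping budget (defaults 100 and 5).
#' @param dropout dropout rate after each conv layer (default 0.01).
#' @param augment_frac fraction of RFD bins randomised per epoch
#'   (default 0.01).
#' @param split list with `train`, `val`, `test` chromosome names;
#'   default: last chromosome = test, previous = validation.
#' @return an `inverter_model`.
#' @export
train_inverter <- function(sim_pair, target_ipls, r, seed = 1L,
                           window_bins = 401L, n_filters = 15L, kernel = 10L,
                           epochs = 100L, patience = 5L, dropout = 0.01,
                           augment_frac = 0.01, split = NULL) {
  stopifnot(inherits(sim_pair, "profile_pair"),
            inherits(target_ipls, "profile"), r >= 0, r <= 1)
  lat <- sim_pair$lattice
  if (is.null(split)) split <- default_split(lat)
  stopifnot(all(unlist(split) %in% lat$chrom_names))
  half <- (window_bins - 1L) %/% 2L

  eff <- effective_ipls(target_ipls, r)
  train_bins <- unlist(lapply(split$train, lattice_chrom_bins, lattice = lat))
  scale <- max(eff$values[train_bins], na.rm = TRUE)
  if (scale <= 0) stop("training target has no mass on the training chromosomes")

  chrom_data <- function(chroms) {
    lapply(chroms, function(ch) {
      idx <- lattice_chrom_bins(lat, ch)
      y <- pmin(eff$values[idx] / scale, 1)
      y[lat$mask[idx]] <- NA_real_
      mrt <- sim_pair$mrt$values[idx]
      rfd <- sim_pair$rfd$values[idx]
      mrt[is.na(mrt)] <- 0
      rfd[is.na(rfd)] <- 0
      L <- length(idx)
      centers <- seq_len(L)
      valid <- centers > half & centers <= L - half & !is.na(y)
      list(mrt = mrt, rfd = rfd, y = y, L = L,
           centers = centers[valid])
    })
  }
  tr <- chrom_data(split$train)
  va <- chrom_data(split$val)

  net <- cnn_new(window_bins, n_filters, kernel, n_channels = 2L, seed = seed)
  st <- adadelta_init(net$w)
  smooth50 <- function(rfd, L) {
    lat1 <- genome_lattice(stats::setNames(L * lat$bin_kb, "c"),
                           bin_kb = lat$bin_kb)
    smooth_profile(profile(rfd, "generic", lat1, normalize = FALSE), 50)$values
  }
  make_X <- function(cd, augment) {
    rfd <- cd$rfd
    if (augment && augment_frac > 0) {
      nb <- max(1L, round(augment_frac * cd$L))
      at <- sample.int(cd$L, nb)
      rfd[at] <- stats::runif(nb, -1, 1)
    }
    cbind(cd$mrt, smooth50(rfd, cd$L))
  }

  set.seed(seed + 1L)
  n_train <- sum(vapply(tr, function(cd) length(cd$centers), 0L))
  if (n_train < 1L) stop("no valid training windows")
  best <- list(loss = Inf, w = net$w, epoch = 0L)
  bad <- 0L
  val_hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    grads <- NULL
    for (cd in tr) {
      X <- make_X(cd, augment = TRUE)
      starts <- cd$centers - half
      fp <- cnn_forward(net, X, starts, dropout = dropout, training = TRUE)
      y <- cd$y[cd$centers]
      dz <- matrix((fp$p - y) / n_train, ncol = 1L)
      g <- cnn_backward(net, fp, dz)
      grads <- if (is.null(grads)) g
               else mapply(function(a, b) a + b, grads, g, SIMPLIFY = FALSE)
    }
    upd <- adadelta_step(net$w, grads, st)
    net$w <- upd$w
    st <- upd$st
    # validation loss without dropout or augmentation
    vl <- 0; nv <- 0L
    for (cd in va) {
      if (!length(cd$centers)) next
      X <- make_X(cd, augment = FALSE)
      fp <- cnn_forward(net, X, cd$centers - half, training = FALSE)
      y <- cd$y[cd$centers]
      vl <- vl + bce_loss(fp$p, y) * length(y)
      nv <- nv + length(y)
    }
    vl <- if (nv > 0) vl / nv else NA_real_
    val_hist <- c(val_hist, vl)
    if (!is.na(vl) && vl < best$loss - 1e-7) {
      best <- list(loss = vl, w = net$w, epoch = ep)
      bad <- 0L
    } else bad <- bad + 1L
    if (bad >= patience) break
  }
  net$w <- best$w
  structure(list(net = net, scale = scale, r = r, split = split,
                 window_bins = as.integer(window_bins),
                 smooth_rfd_kb = 50, val_loss = best$loss,
                 val_history = val_hist, epochs_run = length(val_hist),
                 seed = seed),
            class = "inverter_model")
}

#' @export
print.inverter_model <- function(x, ...) {
  cat(sprintf("inverter_model: window %d bins, %d epoch(s), val loss %.4g\n",
              x$window_bins, x$epochs_run, x$val_loss))
  invisible(x)
}

#' Apply the inverter to an MRT/RFD pair
#'
#' Sliding-window prediction of the initiation landscape for every bin.
#' The RFD channel is smoothed at 50 kb, chromosome edges use reflective
#' padding, masked bins are zeroed and the output is renormalised to unit
#' sum. Chromosomes shorter than the window are skipped with a warning.
#'
#' @param model an `inverter_model`.
#' @param pair a [profile_pair()].
#' @return a `profile` of kind `IPLS`.
#' @export
apply_inverter <- function(model, pair) {
  stopifnot(inherits(model, "inverter_model"), inherits(pair, "profile_pair"))
  lat <- pair$lattice
  half <- (model$window_bins - 1L) %/% 2L
  Xs <- inverter_inputs(pair, model$smooth_rfd_kb)
  out <- numeric(lat$n_bins)
  for (ci in seq_along(lat$chrom_names)) {
    idx <- lattice_chrom_bins(lat, lat$chrom_names[ci])
    L <- length(idx)
    if (L < model$window_bins) {
      warning("chromosome ", lat$chrom_names[ci],
              " is shorter than the inverter window; skipped")
      next
    }
    Xp <- reflect_pad(Xs[[ci]], half)
    fp <- cnn_forward(model$net, Xp, seq_len(L), training = FALSE)
    out[idx] <- fp$p * model$scale
  }
  out[pair$mask | lat$mask] <- 0
  if (sum(out) <= 0) stop("inverter produced an all-zero landscape")
  profile(out, kind = "IPLS", lattice = lat)
}

# Pearson correlation of two MRT profiles at 10 kb (consecutive bin pairs
# averaged within chromosomes); RFD correlations stay at bin resolution
cor_mrt_10kb <- function(a, b, lattice, mask) {
  off <- lattice_chrom_offsets(lattice)
  av <- numeric(0); bv <- numeric(0)
  for (ci in seq_along(lattice$chrom_len_bins)) {
    n <- lattice$chrom_len_bins[ci]
    idx <- seq.int(off[ci] + 1L, off[ci] + n)
    aa <- a[idx]; bb <- b[idx]
    aa[mask[idx]] <- NA; bb[mask[idx]] <- NA
    np <- n %/% 2L
    if (np < 1L) next
    i1 <- seq.int(1L, by = 2L, length.out = np)
    pa <- (aa[i1] + aa[i1 + 1L]) / 2
    pb <- (bb[i1] + bb[i1 + 1L]) / 2
    av <- c(av, pa); bv <- c(bv, pb)
  }
  ok <- !is.na(av) & !is.na(bv)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(av[ok], bv[ok])
}

cor_masked <- function(a, b, mask) {
  ok <- !mask & !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(a[ok], b[ok])
}

# joint score of a simulated ensemble against an experimental pair:
# PCC(MRT) at 10 kb + PCC(RFD) at 5 kb
score_ensemble <- function(ens, pair_exp) {
  mrt_s <- compute_mrt_fractions(ens)
  rfd_s <- compute_rfd(ens)
  mask <- pair_exp$mask | ens$lattice$mask
  pcc_mrt <- cor_mrt_10kb(mrt_s$values, pair_exp$mrt$values,
                          ens$lattice, mask)
  pcc_rfd <- cor_masked(rfd_s$values, pair_exp$rfd$values, mask)
  list(pcc_mrt = pcc_mrt, pcc_rfd = pcc_rfd,
       joint = pcc_mrt + pcc_rfd,
       mrt = mrt_s, rfd = rfd_s)
}

# restrict a pair + IPLS to one chromosome (used by the grid search)
subset_to_chrom <- function(pair, ipls, chrom) {
  lat <- pair$lattice
  idx <- lattice_chrom_bins(lat, chrom)
  lat1 <- genome_lattice(
    stats::setNames(length(idx) * lat$bin_kb, chrom),
    bin_kb = lat$bin_kb, mask = lat$mask[idx])
  mrt1 <- profile(pair$mrt$values[idx], "MRT_fraction", lat1)
  rfd1 <- profile(pair$rfd$values[idx], "RFD", lat1)
  pair1 <- profile_pair(mrt1, rfd1, mask = pair$mask[idx])
  v <- ipls$values[idx]
  v[is.na(v)] <- 0
  ipls1 <- profile(v, "IPLS", lat1)
  list(pair = pair1, ipls = ipls1)
}

#' Grid search over firing-factor density and uniform fraction
#'
#' Simulates a reduced ensemble at every `(rho_F, r)` grid point and scores
#' it against the experimental pair by the sum of the MRT (10 kb) and RFD
#' (5 kb) Pearson correlations; returns the argmax. Fork speed and
#' potential-origin spacing have little effect on the profiles and are kept
#' fixed. A failing grid point is skipped with a warning.
#'
#' @param pair_exp experimental [profile_pair()].
#' @param ipls candidate structured IPLS `profile`.
#' @param rho_grid,r_grid numeric grids for `rho_F` (per Mb) and `r`.
#' @param params_base a [sim_params()] supplying the fixed parameters.
#' @param n_sims ensemble size per grid point (default 20).
#' @param seed RNG seed.
#' @param restrict_chrom optional chromosome name: optimise on that
#'   chromosome only.
#' @return list with `params` (best [sim_params()]), `rho_F`, `r`,
#'   `joint`, and `table` of all evaluated points.
#' @export
grid_search <- function(pair_exp, ipls, rho_grid, r_grid, params_base,
                        n_sims = 20L, seed = 1L, restrict_chrom = NULL) {
  stopifnot(length(rho_grid) >= 1L, length(r_grid) >= 1L)
  if (!is.null(restrict_chrom)) {
    sub <- subset_to_chrom(pair_exp, ipls, restrict_chrom)
    pair_use <- sub$pair; ipls_use <- sub$ipls
  } else {
    pair_use <- pair_exp; ipls_use <- ipls
  }
  lat_use <- pair_use$lattice
  lat_use$mask <- lat_use$mask | pair_use$mask
  tab <- expand.grid(rho_F = rho_grid, r = r_grid)
  tab$pcc_mrt <- tab$pcc_rfd <- tab$joint <- NA_real_
  for (i in seq_len(nrow(tab))) {
    p <- params_base
    p$rho_F <- tab$rho_F[i]
    p$r <- tab$r[i]
    p$n_sims <- as.integer(n_sims)
    res <- tryCatch({
      ens <- simulate_ensemble(lat_use, ipls_use, p, seed = seed)
      score_ensemble(ens, pair_use)
    }, error = function(e) {
      warning("grid point (rho_F = ", tab$rho_F[i], ", r = ", tab$r[i],
              ") failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      tab$pcc_mrt[i] <- res$pcc_mrt
      tab$pcc_rfd[i] <- res$pcc_rfd
      tab$joint[i] <- res$joint
    }
  }
  if (all(is.na(tab$joint))) stop("all grid points failed")
  best <- which.max(tab$joint)
  params <- params_base
  params$rho_F <- tab$rho_F[best]
  params$r <- tab$r[best]
  list(params = params, rho_F = tab$rho_F[best], r = tab$r[best],
       joint = tab$joint[best], table = tab)
}

#' Iterative neural-network inversion of MRT and RFD
#'
#' Alternates (i) grid-search calibration of `(rho_F, r)` given the current
#' landscape, (ii) ensemble simulation of MRT and RFD under that landscape,
#' (iii) training of the convolutional inverter on the simulated pair, and
#' (iv) application of the inverter to the experimental pair to obtain the
#' next landscape. Scores (MRT at 10 kb + RFD at 5 kb Pearson correlations
#' against experiment) are tracked per iteration; the best-scoring
#' landscape is returned. Iteration stops early after two consecutive
#' score decreases.
#'
#' @param pair_exp experimental [profile_pair()].
#' @param i0 initial IPLS `profile` (e.g. from [init_ipls()]).
#' @param n_iter number of improvement iterations (default 4).
#' @param rho_grid,r_grid grids for [grid_search()].
#' @param params_base a [sim_params()] with the fixed parameters.
#' @param n_sims_grid,n_sims ensemble sizes for the grid search and for the
#'   simulation step.
#' @param seed RNG seed.
#' @param restrict_chrom optional chromosome for the grid search.
#' @param nn_args list of extra arguments passed to [train_inverter()].
#' @return an `inversion_result`: `best` (index), `ipls_best` (I_M),
#'   `params_best`, `states` (per-iteration landscape, parameters, scores,
#'   simulated profiles).
#' @export
iterate_inversion <- function(pair_exp, i0, n_iter = 4L, rho_grid, r_grid,
                              params_base, n_sims_grid = 20L, n_sims = 50L,
                              seed = 1L, restrict_chrom = NULL,
                              nn_args = list()) {
  stopifnot(inherits(pair_exp, "profile_pair"), inherits(i0, "profile"))
  if (all(is.na(i0$values) | i0$values == max(i0$values, na.rm = TRUE)))
    stop("flat initial IPLS carries no positional signal")
  lat <- pair_exp$lattice
  states <- list()
  ipls <- i0
  drops <- 0L
  for (it in 0:n_iter) {
    gs <- grid_search(pair_exp, ipls, rho_grid, r_grid, params_base,
                      n_sims = n_sims_grid, seed = seed + 100L * it,
                      restrict_chrom = restrict_chrom)
    p <- gs$params
    p$n_sims <- as.integer(n_sims)
    lat_sim <- lat
    lat_sim$mask <- lat_sim$mask | pair_exp$mask
    ens <- simulate_ensemble(lat_sim, ipls, p, seed = seed + 100L * it + 1L)
    sc <- score_ensemble(ens, pair_exp)
    states[[it + 1L]] <- list(iteration = it, ipls = ipls, params = p,
                              pcc_mrt = sc$pcc_mrt, pcc_rfd = sc$pcc_rfd,
                              joint = sc$joint,
                              mrt_sim = sc$mrt, rfd_sim = sc$rfd)
    if (it >= 1L && sc$joint < states[[it]]$joint) drops <- drops + 1L
    else drops <- 0L
    if (drops >= 2L || it == n_iter) break
    sim_pair <- profile_pair(sc$mrt, sc$rfd, mask = lat_sim$mask)
    model <- do.call(train_inverter, c(list(
      sim_pair = sim_pair, target_ipls = ipls, r = p$r,
      seed = seed + 100L * it + 2L), nn_args))
    ipls <- apply_inverter(model, pair_exp)
  }
  joints <- vapply(states, function(s) s$joint, 0)
  best <- which.max(joints)
  structure(list(best = best, ipls_best = states[[best]]$ipls,
                 params_best = states[[best]]$params,
                 joint_best = joints[best], states = states),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("inversion_result:", length(x$states), "state(s); best iteration",
      x$states[[x$best]]$iteration, "\n")
  for (s in x$states)
    cat(sprintf("  it %d: pcc_mrt = %.3f, pcc_rfd = %.3f, joint = %.3f\n",
                s$iteration, s$pcc_mrt, s$pcc_rfd, s$joint))
  invisible(x)
}
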