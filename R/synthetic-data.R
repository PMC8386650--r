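#' Ground-truth parameter sets for synthetic data
#'
#' Constructors for the truth objects the generators consume. Each
#' validates its invariants and returns a plain list with a class tag.
#'
#' @param agonist,pathway condition labels
#' @param pec50 negative log10 molar potency
#' @param emax maximal response above basal (uBRET span or normalized
#'   current)
#' @param hill_n Hill slope (> 0)
#' @param basal response at zero agonist
#' @param noise_sd i.i.d. Gaussian noise SD on response (>= 0)
#' @return a \code{bret_truth} list
#' @export
bret_truth <- function(agonist, pathway, pec50, emax, hill_n = 1,
                       basal = 0, noise_sd = 0) {
  stopifnot(is.finite(pec50), emax >= 0, hill_n > 0, noise_sd >= 0)
  structure(list(agonist = agonist, pathway = pathway, pec50 = pec50,
                 emax = emax, hill_n = hill_n, basal = basal,
                 noise_sd = noise_sd),
            class = "bret_truth")
}

#' @rdname bret_truth
#' @param em,Basal operational-model system maximum and basal response
#'   (\code{em > Basal})
#' @param n transducer slope (> 0)
#' @param log_ka named numeric: per-agonist log10 functional dissociation
#'   constant (0 for full agonists)
#' @param log_r named list or matrix-like: per-agonist, per-pathway
#'   log10 transduction ratio log(tau/KA); here a data.frame with columns
#'   agonist, pathway, log_r
#' @return an \code{operational_truth} list
#' @export
operational_truth <- function(em, Basal, n, log_ka, log_r) {
  stopifnot(em > Basal, n > 0,
            is.data.frame(log_r),
            all(c("agonist", "pathway", "log_r") %in% names(log_r)),
            all(log_r$agonist %in% names(log_ka)))
  structure(list(em = em, Basal = Basal, n = n, log_ka = log_ka,
                 log_r = log_r),
            class = "operational_truth")
}

#' @rdname bret_truth
#' @param peak peak normalized current (> baseline)
#' @param onset_tau activation time constant, s
#' @param decay_tau desensitization time constant, s (Inf = none)
#' @param baseline agonist-independent current level (0 <= baseline < peak)
#' @param duration trace length, s
#' @param sample_rate sampling rate, Hz
#' @return a \code{girk_truth} list
#' @export
girk_truth <- function(peak = 1, onset_tau = 5, decay_tau = Inf,
                       baseline = 0, duration = 415, sample_rate = 156,
                       noise_sd = 0) {
  stopifnot(duration > 0, sample_rate > 0, baseline >= 0, baseline < peak,
            onset_tau >= 0, decay_tau > 0, noise_sd >= 0)
  structure(list(peak = peak, onset_tau = onset_tau, decay_tau = decay_tau,
                 baseline = baseline, duration = duration,
                 sample_rate = sample_rate, noise_sd = noise_sd),
            class = "girk_truth")
}

#' Default assay concentration grid
#'
#' Nine log-spaced concentrations from 1 pM to 100 uM, spanning every
#' potency handled here (pEC50 4-8).
#'
#' @param n number of points
#' @return concentrations in molar, increasing
#' @export
default_conc_grid <- function(n = 9) {
  10^seq(-12, -4, length.out = n)
}

#' Generate a synthetic BRET concentration-response dataset
#'
#' One row per (truth, concentration, replicate); the noise-free mean at
#' concentration c is \code{hill_response(c, pec50, emax, hill_n, basal)},
#' with i.i.d. Gaussian noise of SD \code{noise_sd} added per row.
#'
#' @param truths list of \code{\link{bret_truth}} objects
#' @param conc_grid strictly positive, sorted concentrations (molar)
#' @param n_rep replicates per concentration (>= 1)
#' @param seed RNG seed (explicit; no global state is left behind)
#' @return long-format concentration-response data.frame
#' @export
generate_bret_dataset <- function(truths, conc_grid = default_conc_grid(),
                                  n_rep = 3, seed = 1) {
  if (inherits(truths, "bret_truth")) truths <- list(truths)
  if (length(conc_grid) == 0) stop("empty concentration grid")
  if (any(conc_grid <= 0)) stop("concentrations must be strictly positive")
  if (is.unsorted(conc_grid, strictly = TRUE)) {
    stop("concentration grid must be strictly increasing")
  }
  stopifnot(n_rep >= 1)
  out <- withr::with_seed(seed, {
    parts <- lapply(truths, function(tr) {
      mu <- hill_response(conc_grid, tr$pec50, tr$emax, tr$hill_n, tr$basal)
      d <- expand.grid(replicate = seq_len(n_rep), conc_M = conc_grid,
                       KEEP.OUT.ATTRS = FALSE)
      d$agonist <- tr$agonist
      d$pathway <- tr$pathway
      d$response <- rep(mu, each = n_rep) +
        stats::rnorm(nrow(d), sd = tr$noise_sd)
      d
    })
    do.call(rbind, parts)
  })
  out <- out[, c("agonist", "pathway", "conc_M", "replicate", "response")]
  rownames(out) <- NULL
  out
}

#' Generate synthetic data from the operational model of agonism
#'
#' Noise-free means follow the Black-Leff operational equation (see
#' \code{\link{operational_response}}); one row per (agonist, pathway,
#' concentration, replicate).
#'
#' @param truth an \code{\link{operational_truth}}
#' @param conc_grid strictly positive, sorted molar concentrations
#' @param n_rep replicates per point
#' @param noise_sd Gaussian noise SD on response
#' @param seed RNG seed
#' @return long-format concentration-response data.frame
#' @export
generate_operational_dataset <- function(truth,
                                         conc_grid = default_conc_grid(),
                                         n_rep = 3, noise_sd = 0, seed = 1) {
  stopifnot(inherits(truth, "operational_truth"))
  if (length(conc_grid) == 0) stop("empty concentration grid")
  if (any(conc_grid <= 0)) stop("concentrations must be strictly positive")
  withr::with_seed(seed, {
    parts <- lapply(seq_len(nrow(truth$log_r)), function(i) {
      ag <- truth$log_r$agonist[i]
      mu <- operational_response(
        conc_grid, em = truth$em, Basal = truth$Basal, n = truth$n,
        log_ka = truth$log_ka[[ag]], log_r = truth$log_r$log_r[i]
      )
      d <- expand.grid(replicate = seq_len(n_rep), conc_M = conc_grid,
                       KEEP.OUT.ATTRS = FALSE)
      d$agonist <- ag
      d$pathway <- truth$log_r$pathway[i]
      d$response <- rep(mu, each = n_rep) + stats::rnorm(nrow(d), sd = noise_sd)
      d
    })
    out <- do.call(rbind, parts)
    out <- out[, c("agonist", "pathway", "conc_M", "replicate", "response")]
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic GIRK current trace
#'
#' Current follows an activation-times-desensitization product,
#' \deqn{I(t) = peak (1 - e^{-t/\tau_{on}})
#'   (b/peak + (1 - b/peak) e^{-t/\tau_{dec}}) + \epsilon,}
#' sampled on a uniform grid of \code{floor(duration * rate)} points.
#'
#' @param truth a \code{\link{girk_truth}}
#' @param seed RNG seed
#' @return data.frame with columns \code{time_s}, \code{current}
#' @export
generate_girk_trace <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "girk_truth"))
  n <- floor(truth$duration * truth$sample_rate)
  if (n < 2) stop("duration * sample_rate must give at least 2 samples")
  t <- seq(0, by = 1 / truth$sample_rate, length.out = n)
  onset <- if (truth$onset_tau == 0) 1 else 1 - exp(-t / truth$onset_tau)
  frac <- truth$baseline / truth$peak
  decay <- frac + (1 - frac) * exp(-t / truth$decay_tau)
  cur <- truth$peak * onset * decay
  if (truth$noise_sd > 0) {
    cur <- withr::with_seed(seed,
                            cur + stats::rnorm(n, sd = truth$noise_sd))
  }
  data.frame(time_s = t, current = cur)
}

#' Decay time constant giving a target residual fraction
#'
#' Inverts the trace model of \code{\link{generate_girk_trace}}: finds the
#' desensitization tau such that the peak-normalized current at
#' \code{t_end} equals \code{residual}. With instantaneous onset and zero
#' baseline this is the closed form \code{t_end / log(1/residual)};
#' otherwise the normalization by the trace's own maximum is accounted for
#' numerically.
#'
#' @param residual target fraction of peak remaining at \code{t_end},
#'   in (0, 1)
#' @param t_end time of the readout, s
#' @param onset_tau,baseline,peak trace-model parameters
#' @return decay tau in seconds
#' @export
decay_tau_for_residual <- function(residual, t_end = 415, onset_tau = 0,
                                   baseline = 0, peak = 1) {
  stopifnot(residual > 0, residual < 1, t_end > 0)
  if (onset_tau == 0 && baseline == 0) {
    return(t_end / log(1 / residual))
  }
  f <- function(tau) {
    tr <- generate_girk_trace(girk_truth(peak = peak, onset_tau = onset_tau,
                                         decay_tau = tau, baseline = baseline,
                                         duration = t_end,
                                         sample_rate = 156))
    tr$current[nrow(tr)] / max(tr$current) - residual
  }
  stats::uniroot(f, c(t_end / 50, t_end * 50), tol = 1e-8)$root
}

#' Generate a per-frame coordinate fixture with planted contact rates
#'
#' Builds a long coordinate table (frame, atom_id, role, x, y, z) in which
#' each requested ligand-residue pair is placed within \code{cutoff}
#' (uniform in [0.7, 1] x cutoff) with Bernoulli(target) probability per
#' frame, and far apart (3-5 x cutoff) otherwise. Empirical contact
#' frequency converges to the target as frames grow.
#'
#' @param n_frames number of frames
#' @param pairs data.frame with columns \code{ligand_atom},
#'   \code{residue}, \code{target} (frequency in [0, 1])
#' @param cutoff contact cutoff, Angstrom (> 0)
#' @param seed RNG seed
#' @return data.frame with columns frame, atom_id, role, x, y, z
#' @export
generate_contact_fixture <- function(n_frames, pairs, cutoff = 3.5,
                                     seed = 1) {
  stopifnot(n_frames >= 1, is.data.frame(pairs),
            all(c("ligand_atom", "residue", "target") %in% names(pairs)))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(pairs$target < 0 | pairs$target > 1)) {
    stop("target frequencies must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    parts <- lapply(seq_len(nrow(pairs)), function(i) {
      # pair i lives on its own axis offset so pairs never interfere
      base <- c(100 * i, 0, 0)
      hit <- stats::runif(n_frames) < pairs$target[i]
      d <- ifelse(hit, stats::runif(n_frames, 0.7, 1) * cutoff,
                  stats::runif(n_frames, 3, 5) * cutoff)
      lig <- data.frame(frame = seq_len(n_frames),
                        atom_id = pairs$ligand_atom[i], role = "ligand",
                        x = base[1], y = base[2], z = base[3])
      res <- data.frame(frame = seq_len(n_frames),
                        atom_id = pairs$residue[i], role = "residue",
                        x = base[1] + d, y = base[2], z = base[3])
      rbind(lig, res)
    })
    out <- do.call(rbind, parts)
    out <- out[order(out$frame, out$role, out$atom_id), ]
    rownames(out) <- NULL
    out
  })
}
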