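#' Specify a synthetic two-group cohort
#'
#' Defines the study conditions for the synthetic cohort: two groups of
#' subjects whose band-limited phase-lag coupling differs in spatial
#' organisation, a log-normal metabolite table with planted group effects,
#' and depression-like scores. The coupled subnetwork of each subject is a
#' ring lattice over the 20 canonical electrodes whose edges are rewired to
#' random long-range pairs with a per-subject probability `c` drawn from a
#' group-specific Beta distribution; higher rewiring randomises the
#' network (shorter paths, higher global efficiency), emulating the
#' topology shift reported in subclinical depression. One metabolite
#' feature is rank-linked to `c` at a target Spearman correlation.
#'
#' @param n_group_a,n_group_b Subject counts (group A is the
#'   high-rewiring, depressed-like group).
#' @param band Frequency band carrying the planted coupling.
#' @param coupling_a,coupling_b Optional explicit [coupling_spec()]s used
#'   for every subject of the group; when `NULL` (default) the ring +
#'   rewiring model below is used.
#' @param rewire_a,rewire_b Beta shape pairs for the per-subject rewiring
#'   probability in each group.
#' @param ring_k Ring-lattice half-degree (k = 2 gives the 40-edge
#'   Watts-Strogatz lattice, filling the binary graph at sparsity
#'   40/190 ~ 0.21).
#' @param n_slots Number of rotating activation windows: couplings are
#'   intermittent, and a proper edge colouring assigns pairs sharing a
#'   channel to different windows so simultaneous pair sources do not
#'   dilute each other.
#' @param pair_q Mean sign-inconsistency of coupled pairs (PLI ~ 1 - 2q);
#'   jittered per pair by +/-0.03.
#' @param base_amplitude,noise_sd Oscillator / noise amplitudes in uV.
#' @param fs,duration_s Sampling rate and duration of each recording.
#' @param n_metabolites Number of metabolite features.
#' @param affected_features Indices shifted by `log_fold_change` (natural
#'   log) in group A.
#' @param log_fold_change Planted log-scale group shift.
#' @param score_link `list(feature, rho)`: feature index rank-linked to the
#'   per-subject rewiring probability at target Spearman `rho`.
#' @param sigma_log Log-scale noise SD of intensities.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return Object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_group_a = 40, n_group_b = 38,
                              band = "beta1",
                              coupling_a = NULL, coupling_b = NULL,
                              rewire_a = c(7, 3), rewire_b = c(1.5, 8.5),
                              ring_k = 2, pair_q = 0.02,
                              n_slots = 4,
                              base_amplitude = 8, noise_sd = 1.6,
                              fs = 1024, duration_s = 60,
                              n_metabolites = 50,
                              affected_features = 6:10,
                              log_fold_change = 1.0,
                              score_link = list(feature = 1, rho = 0.7),
                              sigma_log = 0.5, seed = 1) {
  stopifnot(n_group_a > 0, n_group_b > 0, n_metabolites > 0)
  if (!all(affected_features %in% seq_len(n_metabolites))) {
    stop("affected_features outside 1..n_metabolites")
  }
  if (abs(score_link$rho) > 1) stop("|target rho| must be <= 1")
  if (!(score_link$feature %in% seq_len(n_metabolites))) {
    stop("score_link feature index out of range")
  }
  structure(as.list(environment()), class = "synth_cohort_spec")
}

# ring lattice pairs over n nodes: (i, i+1), ..., (i, i+k) modulo n
ring_pairs <- function(n, k) {
  out <- NULL
  for (d in seq_len(k)) {
    j <- ((seq_len(n) - 1 + d) %% n) + 1
    out <- rbind(out, cbind(pmin(seq_len(n), j), pmax(seq_len(n), j)))
  }
  unique(out)
}

# Watts-Strogatz style rewiring: each rewirable edge is replaced, with
# probability c, by a uniformly random absent pair.
rewire_pairs <- function(pairs, n, c, rewirable = seq_len(nrow(pairs))) {
  key <- function(p) p[, 1] * 1000 + p[, 2]
  for (e in rewirable) {
    if (stats::runif(1) < c) {
      repeat {
        ij <- sort(sample.int(n, 2))
        if (!(ij[1] * 1000 + ij[2]) %in% key(pairs)) {
          pairs[e, ] <- ij
          break
        }
      }
    }
  }
  pairs
}

# greedy proper edge coloring into at most n_slots colors; when a vertex
# neighbourhood exhausts the palette the edge gets a random colour (a
# collision merely weakens that pair's expressed PLI)
edge_coloring <- function(pairs, n, n_slots) {
  used <- matrix(FALSE, n, n_slots)
  col <- integer(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    free <- which(!(used[pairs[e, 1], ] | used[pairs[e, 2], ]))
    col[e] <- if (length(free)) free[1] else sample.int(n_slots, 1)
    used[pairs[e, 1], col[e]] <- TRUE
    used[pairs[e, 2], col[e]] <- TRUE
  }
  col - 1L
}

# Per-subject coupling spec from the backbone + variable-tier model: the
# nearest-neighbour cycle (first ring) is a fixed backbone common to all
# subjects; only the longer-range rings are rewired with probability c, so
# between-subject topology differences are carried entirely by the
# variable tier and are expressed once the binary graph grows past the
# backbone-fill sparsity.
subject_coupling <- function(spec, c_i, montage) {
  nch <- length(montage$labels)
  ring <- ring_pairs(nch, spec$ring_k)
  d_ring <- pmin(abs(ring[, 1] - ring[, 2]),
                 nch - abs(ring[, 1] - ring[, 2]))
  variable <- which(d_ring > 1)
  pr <- rewire_pairs(ring, nch, c_i, rewirable = variable)
  data.frame(
    i = montage$labels[pr[, 1]],
    j = montage$labels[pr[, 2]],
    lag = stats::runif(nrow(pr), pi / 3, 2 * pi / 3),
    q = pmin(0.5, pmax(0, spec$pair_q + stats::runif(nrow(pr), -0.02, 0.02))),
    slot = edge_coloring(pr, nch, spec$n_slots)
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject rewiring probabilities, EEG-like recordings with the
#' planted coupling topology, a log-normal metabolite table with planted
#' fold changes and one network-linked feature, and depression-like scores
#' that increase with the rewiring probability. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [synth_cohort_spec()].
#' @param eeg If `FALSE`, skip the (expensive) recordings and return only
#'   metabolites, scores, and ground truth.
#' @return List with `recordings` (list of [recording] or `NULL`),
#'   `labels` (factor `A`/`B`), `metabolites` (a [metabolite_table()]),
#'   `scores` (`data.frame` subject/score) and `truth` (per-subject
#'   rewiring probabilities, couplings, planted indices).
#' @export
generate_cohort <- function(spec, eeg = TRUE) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  set.seed(spec$seed)
  mont <- montage_1020()
  n <- spec$n_group_a + spec$n_group_b
  labels <- factor(rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b)))
  ids <- sprintf("S%03d", seq_len(n))

  # latent copula variable -> group-specific rewiring probability
  z_c <- stats::rnorm(n)
  shapes <- rbind(spec$rewire_a, spec$rewire_b)[as.integer(labels), ]
  c_i <- stats::qbeta(stats::pnorm(z_c), shapes[, 1], shapes[, 2])

  # coupled subnetworks first: the linked metabolite feature tracks the
  # true planted-graph global efficiency (the network property expressed
  # at the lattice-fill sparsity), so the correlation scan has a known peak
  couplings <- vector("list", n)
  eg_true <- numeric(n)
  for (s in seq_len(n)) {
    if (is.null(spec$coupling_a)) {
      pr <- subject_coupling(spec, c_i[s], mont)
      cs <- coupling_spec(spec$band, pr, spec$base_amplitude, spec$noise_sd,
                          n_slots = spec$n_slots, slot_len_s = 2)
    } else {
      cs <- if (labels[s] == "A") spec$coupling_a else spec$coupling_b
    }
    couplings[[s]] <- cs
    A <- matrix(0L, length(mont$labels), length(mont$labels),
                dimnames = list(mont$labels, mont$labels))
    A[cbind(cs$pairs$i, cs$pairs$j)] <- 1L
    A[cbind(cs$pairs$j, cs$pairs$i)] <- 1L
    eg_true[s] <- global_efficiency(A)
  }
  fill_sparsity <- nrow(couplings[[1]]$pairs) /
    (length(mont$labels) * (length(mont$labels) - 1) / 2)

  # metabolites: log-normal, planted fold changes, one linked feature
  rho <- spec$score_link$rho
  r_g <- 2 * sin(pi * rho / 6)  # Gaussian copula scale for Spearman target
  z_e <- stats::qnorm((rank(eg_true) - 0.5) / n)
  mu <- stats::runif(spec$n_metabolites, log(1e4), log(1e6))
  Z <- matrix(stats::rnorm(n * spec$n_metabolites), n, spec$n_metabolites)
  lf <- spec$score_link$feature
  Z[, lf] <- r_g * z_e + sqrt(1 - r_g^2) * Z[, lf]
  shift <- outer(labels == "A", seq_len(spec$n_metabolites) %in%
                   spec$affected_features) * spec$log_fold_change
  X <- exp(sweep(spec$sigma_log * Z + shift, 2, mu, "+"))
  metab <- metabolite_table(X, sample_ids = ids, group = labels,
                            features = sprintf("met_%02d",
                                               seq_len(spec$n_metabolites)))

  scores <- data.frame(
    subject = ids,
    score = pmax(0, round(3 + 24 * c_i + stats::rnorm(n, 0, 1.5)))
  )

  recs <- NULL
  if (eeg) {
    recs <- vector("list", n)
    for (s in seq_len(n)) {
      recs[[s]] <- generate_recording(mont, spec$fs, spec$duration_s,
                                      couplings[[s]])
    }
    names(recs) <- ids
  }

  list(recordings = recs, labels = labels, subjects = ids,
       metabolites = metab, scores = scores,
       truth = list(rewire = c_i, couplings = couplings,
                    eg_true = eg_true, fill_sparsity = fill_sparsity,
                    affected = spec$affected_features,
                    linked_feature = lf, target_rho = rho,
                    band = as_band(spec$band)))
}
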