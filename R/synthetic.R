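# Synthetic training panels and screening libraries with planted
# descriptor structure.
#
# The generator emulates the shape of a receptor screening study — a
# medium-sized electrophysiology panel (odors x receptors, spikes/s) with
# a companion molecular-descriptor table, and a larger screening library —
# while planting a known low-dimensional structure: each receptor's
# response is a Gaussian kernel of the compound's distance from a receptor
# prototype within a small planted descriptor subspace, so selection and
# screening results can be checked against ground truth. The compounds are
# statistical stand-ins, not molecules.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the scale of a published antennal receptor panel:
#' 109 training odors, a 200-descriptor table (a desk-scale stand-in for a
#' several-thousand-descriptor commercial set), and four receptors with
#' disjoint three-descriptor planted subspaces and varied tuning breadth —
#' two broadly tuned receptors whose response ceilings (250/200 spikes/s)
#' and kernel scales give active-set sizes typical of antennal panels, and
#' two narrowly tuned receptors (`Or3`, `Or4`) with marginal 51 spikes/s
#' ceilings and kernel scale 2.2, whose active sets are compact cliques
#' around their prototypes; the latter is the regime in which
#' descriptor-subset recovery is identifiable (see the methods vignette). Each prototype is anchored
#' at the planted coordinates of one training compound, playing the role
#' of the receptor's best known ligand.
#'
#' @param n_train number of training odors (>= 3).
#' @param n_library number of background screening-library compounds.
#' @param n_descriptors number of molecular descriptors.
#' @param receptors list of receptor definitions; each a list with `id`,
#'   `s_star` (descriptor indices of the planted subspace), `tau` (kernel
#'   scale), `a_max` (response at the prototype, spikes/s), `sigma`
#'   (response noise SD, spikes/s) and either `prototype` (numeric vector,
#'   one value per planted descriptor) or `anchor` (training-compound row
#'   index whose planted coordinates become the prototype).
#' @param planted_fraction fraction of `n_library` added per receptor as
#'   near-prototype compounds (default 0.02).
#' @param library_jitter SD of the planted compounds' displacement from the
#'   prototype within the planted subspace (default 0.1).
#' @param seed integer seed; identical configs generate identical data.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_train = 109, n_library = 1000,
                             n_descriptors = 200, receptors = NULL,
                             planted_fraction = 0.02, library_jitter = 0.1,
                             seed = 1) {
  if (is.null(receptors)) {
    receptors <- list(
      list(id = "Or1", s_star = 1:3, anchor = 1L, tau = 1.0, a_max = 250, sigma = 0),
      list(id = "Or2", s_star = 4:6, anchor = 2L, tau = 0.8, a_max = 200, sigma = 0),
      list(id = "Or3", s_star = 7:9, anchor = 3L, tau = 2.2, a_max = 51, sigma = 0),
      list(id = "Or4", s_star = 10:12, anchor = 4L, tau = 2.2, a_max = 51, sigma = 0))
  }
  for (r in receptors) {
    stopifnot(!is.null(r$id), !is.null(r$s_star), !is.null(r$tau),
              !is.null(r$a_max))
    if (r$a_max <= 0) stop("a_max must be positive", call. = FALSE)
    if (!is.null(r$sigma) && r$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
    if (max(r$s_star) > n_descriptors) {
      stop("planted subspace exceeds descriptor count", call. = FALSE)
    }
  }
  structure(list(n_train = n_train, n_library = n_library,
                 n_descriptors = n_descriptors, receptors = receptors,
                 planted_fraction = planted_fraction,
                 library_jitter = library_jitter, seed = as.integer(seed)),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

receptor_prototype <- function(r, X) {
  if (!is.null(r$prototype)) return(r$prototype)
  if (!is.null(r$anchor)) return(X[r$anchor, r$s_star])
  stop("receptor needs a 'prototype' or an 'anchor'", call. = FALSE)
}

kernel_response <- function(X, r) {
  proto <- receptor_prototype(r, X)
  d2 <- colSums((t(X[, r$s_star, drop = FALSE]) - proto)^2)
  r$a_max * exp(-d2 / (2 * r$tau^2))
}

#' Generate a synthetic training panel
#'
#' Descriptor values are drawn i.i.d. standard normal (fixed column-major
#' draw order); the response of a compound at a receptor is
#' `a_max * exp(-d^2 / (2 tau^2)) + eps`, clipped at 0, where `d` is the
#' compound's Euclidean distance from the receptor prototype restricted to
#' the planted subspace and `eps ~ N(0, sigma)`. Responses below baseline
#' are not simulated.
#'
#' @param config `synthetic_config`.
#' @return list with `activity` (odor-by-receptor matrix), `descriptors`
#'   (raw compound-by-descriptor matrix) and `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_train < 3) stop("need at least 3 training compounds", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_train; p <- config$n_descriptors
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("odor%03d", seq_len(n)),
                                sprintf("d%03d", seq_len(p))))
    act <- vapply(config$receptors, function(r) {
      a <- kernel_response(X, r)
      sigma <- if (is.null(r$sigma)) 0 else r$sigma
      if (sigma > 0) a <- a + stats::rnorm(n, 0, sigma)
      pmax(0, a)
    }, numeric(n))
    colnames(act) <- vapply(config$receptors, `[[`, "", "id")
    rownames(act) <- rownames(X)
    list(activity = act, descriptors = X, config = config)
  })
}

#' Generate a synthetic screening library
#'
#' Background compounds are drawn from the same standard-normal descriptor
#' distribution as the training panel; in addition, a configurable fraction
#' per receptor is planted near that receptor's prototype (prototype plus
#' `N(0, library_jitter^2)` within the planted subspace, background
#' elsewhere) so screening recovery can be verified. The companion
#' compound records carry toy molecular weights and element compositions
#' (statistical stand-ins) for exercising admission filters.
#'
#' @param config `synthetic_config`.
#' @return list with `descriptors` (library compound-by-descriptor
#'   matrix), `compounds` (`compound_library` with toy properties;
#'   `source_tag` names the seeding receptor or `"background"`) and
#'   `planted` (data.frame `id`, `receptor`).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  panel_X <- generate_panel(config)$descriptors  # prototypes may be anchored
  with_seed(config$seed + 1L, {
    p <- config$n_descriptors
    n_bg <- config$n_library
    n_pl <- floor(config$planted_fraction * config$n_library)
    rs <- config$receptors
    n_tot <- n_bg + n_pl * length(rs)
    X <- matrix(stats::rnorm(n_tot * p), n_tot, p,
                dimnames = list(sprintf("lib%05d", seq_len(n_tot)),
                                sprintf("d%03d", seq_len(p))))
    tags <- rep("background", n_tot)
    if (n_pl > 0) {
      row <- n_bg
      for (r in rs) {
        proto <- receptor_prototype(r, panel_X)
        idx <- row + seq_len(n_pl)
        X[idx, r$s_star] <- rep(proto, each = n_pl) +
          stats::rnorm(n_pl * length(r$s_star), 0, config$library_jitter)
        tags[idx] <- r$id
        row <- row + n_pl
      }
    }
    if (n_tot == 0) {
      return(list(descriptors = X, compounds = compound_library(character(0)),
                  planted = data.frame(id = character(), receptor = character(),
                                       stringsAsFactors = FALSE)))
    }
    atoms <- list(c("C", "H"), c("C", "H", "O"), c("C", "H", "O", "N"),
                  c("C", "H", "S"), c("C", "H", "O", "Cl"),
                  c("C", "H", "Br"), c("C", "H", "O", "F"))
    compounds <- compound_library(
      id = rownames(X),
      mol_weight = exp(stats::rnorm(n_tot, log(120), 0.35)),
      atom_set = sample(atoms, n_tot, replace = TRUE),
      source_tag = tags)
    list(descriptors = X, compounds = compounds,
         planted = data.frame(id = rownames(X)[tags != "background"],
                              receptor = tags[tags != "background"],
                              stringsAsFactors = FALSE))
  })
}

#' A perfectly separable benchmark panel
#'
#' Degenerate single-receptor instance for validating the cross-validation
#' machinery: the active odors sit exactly at the receptor prototype along
#' one signal descriptor (response `a_max`), while every inactive odor is
#' kept at least `margin` away from the prototype in that coordinate, so
#' active and inactive compounds are separated by construction and a
#' correct pipeline must score a perfect ROC. All remaining descriptors
#' are standard-normal noise.
#'
#' @param n_compounds total odors.
#' @param n_descriptors total descriptors (first one carries the signal).
#' @param n_actives number of active odors (placed at the prototype).
#' @param margin minimum |signal coordinate| of inactive odors (default 2;
#'   inactives are spread uniformly between `margin` and `margin + 3`).
#' @param a_max response ceiling in spikes/s (default 250).
#' @param seed integer seed.
#' @return list with `activity` (one receptor, `OrSep`), `descriptors`,
#'   and `actives` (the planted active odor ids).
#' @export
synthetic_separable_panel <- function(n_compounds = 100, n_descriptors = 50,
                                      n_actives = 20, margin = 2,
                                      a_max = 250, seed = 1) {
  stopifnot(n_actives >= 2, n_compounds > n_actives)
  with_seed(seed, {
    n <- n_compounds; p <- n_descriptors
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("odor%03d", seq_len(n)),
                                sprintf("d%03d", seq_len(p))))
    X[seq_len(n_actives), 1] <- 0
    n_in <- n - n_actives
    X[n_actives + seq_len(n_in), 1] <-
      sample(c(-1, 1), n_in, replace = TRUE) * stats::runif(n_in, margin, margin + 3)
    a <- a_max * exp(-X[, 1]^2 / 2)
    activity <- matrix(a, ncol = 1,
                       dimnames = list(rownames(X), "OrSep"))
    list(activity = activity, descriptors = X,
         actives = rownames(X)[seq_len(n_actives)])
  })
}
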