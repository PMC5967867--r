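#' Specify an allosteric modulator
#'
#' A modulator is described by its association rate, its dissociation rate
#' from the reference state (the fully agonist-bound, closed receptor), a
#' gating factor applied multiplicatively to the channel opening rate in
#' modulator-bound states, and a state-dependence factor expressing how much
#' weaker the modulator binds to receptors that have not yet bound all of
#' their agonist molecules (use dependence). Dissociation rates from all
#' other states are never set by the user: they are derived from thermodynamic
#' cycle closure so that every cycle in the expanded state graph satisfies
#' microscopic reversibility (see [receptor_scheme()]).
#'
#' @param name Label for the modulator (e.g. `"PAM"`, `"NAM"`).
#' @param role Either `"PAM"` or `"NAM"`.
#' @param k_on Association rate constant, 1/(uM s). Must be positive.
#' @param k_off_reference Dissociation rate from the fully agonist-bound
#'   closed state, 1/s. Must be positive. `k_off_reference / k_on` is the
#'   reference dissociation constant K_ref in uM.
#' @param gating_factor Multiplicative factor applied to the opening rate
#'   beta while the modulator is bound. `> 1` potentiates, `< 1` inhibits,
#'   `1` is a silent (binding-only) ligand. Must be positive.
#' @param state_dependence_factor Fold reduction in affinity (fold increase
#'   in dissociation rate) for receptors that are not fully agonist-bound.
#'   Must be `>= 1`; large values reproduce the use dependence of modulators
#'   that bind with high affinity only once both co-agonists are bound.
#' @return An object of class `"modulator_spec"`.
#' @seealso [receptor_scheme()]
#' @export
modulator_spec <- function(name, role = c("PAM", "NAM"), k_on, k_off_reference,
                           gating_factor = 1, state_dependence_factor = 100) {
  role <- match.arg(role)
  for (fld in c("k_on", "k_off_reference", "gating_factor")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("modulator_spec: field '", fld, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(state_dependence_factor) || length(state_dependence_factor) != 1L ||
      !is.finite(state_dependence_factor) || state_dependence_factor < 1) {
    stop("modulator_spec: field 'state_dependence_factor' must be >= 1",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), role = role, k_on = k_on,
         k_off_reference = k_off_reference, gating_factor = gating_factor,
         state_dependence_factor = state_dependence_factor),
    class = "modulator_spec"
  )
}

#' @export
print.modulator_spec <- function(x, ...) {
  cat(sprintf("Modulator '%s' (%s): k_on %.4g /(uM s), k_off(ref) %.4g /s, K_ref %.4g uM\n",
              x$name, x$role, x$k_on, x$k_off_reference,
              x$k_off_reference / x$k_on))
  cat(sprintf("  gating factor %.4g, state-dependence factor %.4g\n",
              x$gating_factor, x$state_dependence_factor))
  invisible(x)
}

#' Build a Markov receptor gating scheme with modulator layers
#'
#' Constructs the state graph of an agonist-gated receptor: a linear chain of
#' agonist-binding steps ending in a closed/open gating step, replicated into
#' modulator-occupancy layers. With topology `"MODEL1"` the layers are
#' \{free, NAM-bound, PAM-bound\} (mutually exclusive binding: a single site
#' accommodates either modulator but not both); with `"MODEL2"` a fourth,
#' doubly occupied layer is added (independent sites).
#'
#' Rates inside modulator-bound layers are derived, not free parameters:
#' the opening rate is `beta * gating_factor` (product over bound
#' modulators), and the final agonist dissociation step is divided by the
#' state-dependence factor. Modulator dissociation is `k_off_reference` from
#' the fully agonist-bound closed state, `k_off_reference / gating_factor`
#' from the open state, and `state_dependence_factor * k_off_reference` from
#' every sub-saturated state. These choices close every thermodynamic cycle,
#' so the expanded graph satisfies microscopic reversibility by construction
#' (verified on build via [check_reversibility()]).
#'
#' @param topology `"MODEL1"` (shared, mutually exclusive site) or
#'   `"MODEL2"` (independent sites).
#' @param agonist_on,agonist_off Per-site agonist association (1/(uM s)) and
#'   dissociation (1/s) rate constants.
#' @param beta,alpha Opening and closing rates, 1/s. The unliganded-gate
#'   equilibrium constant `beta/alpha` sets the open probability at
#'   saturating agonist.
#' @param pam,nam [modulator_spec()] objects (either may be `NULL` to omit
#'   that modulator).
#' @param n_agonist_sites Number of sequential agonist binding steps
#'   (default 2). `0` gives a binding-only receptor with a single base state
#'   and no gating step (useful as an analytic two-state reduction).
#' @param gating Logical; include the closed/open gating step (default `TRUE`
#'   when `n_agonist_sites > 0`).
#' @param statistical_factors Multiplicities for the agonist binding steps;
#'   defaults to `n_agonist_sites:1` on association (and `1:n_agonist_sites`
#'   on dissociation), i.e. 2/1 for the default two-step chain.
#' @return An object of class `"receptor_scheme"` with components
#'   `base_states`, `layers`, `states` (expanded labels), `open_states`, the
#'   rate parameters and topology.
#' @examples
#' sch <- default_scheme("MODEL1")
#' sch
#' nrow_q <- length(sch$states)   # 12 states: 4 base x 3 layers
#' @export
receptor_scheme <- function(topology = c("MODEL1", "MODEL2"),
                            agonist_on = 10, agonist_off = 50,
                            beta = 5, alpha = 500,
                            pam = NULL, nam = NULL,
                            n_agonist_sites = 2,
                            gating = n_agonist_sites > 0,
                            statistical_factors = NULL) {
  topology <- match.arg(topology)
  rates <- c(agonist_on = agonist_on, agonist_off = agonist_off)
  if (gating) rates <- c(rates, beta = beta, alpha = alpha)
  for (fld in names(rates)) {
    v <- rates[[fld]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("receptor_scheme: rate '", fld, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (!is.null(pam) && !inherits(pam, "modulator_spec")) {
    stop("receptor_scheme: 'pam' must be a modulator_spec", call. = FALSE)
  }
  if (!is.null(nam) && !inherits(nam, "modulator_spec")) {
    stop("receptor_scheme: 'nam' must be a modulator_spec", call. = FALSE)
  }
  if (n_agonist_sites < 0 || n_agonist_sites != round(n_agonist_sites)) {
    stop("receptor_scheme: n_agonist_sites must be a non-negative integer",
         call. = FALSE)
  }
  if (gating && n_agonist_sites == 0 && is.null(statistical_factors)) {
    # allowed: single ligand-free binding chain of length 1 plus a gate would
    # be ambiguous; forbid to keep state labels well defined
    stop("receptor_scheme: gating requires n_agonist_sites >= 1", call. = FALSE)
  }
  if (is.null(statistical_factors)) {
    statistical_factors <- if (n_agonist_sites > 0) seq(n_agonist_sites, 1) else numeric(0)
  }
  if (length(statistical_factors) != n_agonist_sites) {
    stop("receptor_scheme: statistical_factors must have one entry per agonist step",
         call. = FALSE)
  }

  # base chain labels: R, RA, RA2, ..., O
  if (n_agonist_sites == 0) {
    base_states <- "R"
  } else {
    base_states <- c("R", paste0("RA", c("", if (n_agonist_sites > 1) 2:n_agonist_sites)))
    if (gating) base_states <- c(base_states, "O")
  }
  open_states <- if (gating) "O" else character(0)

  mods <- list()
  if (!is.null(nam)) mods[[nam$name]] <- nam
  if (!is.null(pam)) mods[[pam$name]] <- pam
  if (length(mods) && anyDuplicated(names(mods))) {
    stop("receptor_scheme: modulators must have distinct names", call. = FALSE)
  }

  layers <- list(character(0))
  for (nm in names(mods)) layers <- c(layers, list(nm))
  if (topology == "MODEL2" && length(mods) == 2) {
    layers <- c(layers, list(names(mods)))
  }

  layer_label <- vapply(layers, function(l) {
    if (!length(l)) "" else paste0(".", paste(l, collapse = ""))
  }, character(1))
  # ordering: layer-major (all base states of layer 1, then layer 2, ...)
  states <- unlist(lapply(layer_label, function(suf) paste0(base_states, suf)),
                   use.names = FALSE)

  sch <- structure(
    list(topology = topology, base_states = base_states,
         open_states = open_states, layers = layers, states = states,
         agonist_on = agonist_on, agonist_off = agonist_off,
         beta = if (gating) beta else NA_real_,
         alpha = if (gating) alpha else NA_real_,
         gating = gating, n_agonist_sites = n_agonist_sites,
         statistical_factors = statistical_factors, modulators = mods),
    class = "receptor_scheme"
  )
  # microscopic reversibility is guaranteed by construction; assert anyway
  chk <- check_reversibility(sch)
  if (!isTRUE(chk$reversible)) {
    stop("receptor_scheme: internal error, cycle closure violated (max relative ",
         "imbalance ", format(chk$max_imbalance), ")", call. = FALSE)
  }
  sch
}

#' Default demonstration scheme
#'
#' The documented default parameterization: a two-step agonist chain with
#' statistical factors 2/1, a low open probability gate (beta 5 /s, alpha
#' 500 /s), one NAM (reference K 0.2 uM, gating factor 0.14, i.e. 14 percent
#' residual current at saturation) and one PAM (reference K 2 uM, gating
#' factor 2.5, i.e. 250 percent of control at saturation), both strongly
#' use-dependent.
#'
#' @param topology `"MODEL1"` or `"MODEL2"`.
#' @param ... Overrides passed on to [receptor_scheme()].
#' @return A `"receptor_scheme"`.
#' @export
default_scheme <- function(topology = c("MODEL1", "MODEL2"), ...) {
  topology <- match.arg(topology)
  args <- list(
    topology = topology,
    nam = modulator_spec("N", "NAM", k_on = 1, k_off_reference = 0.2,
                         gating_factor = 0.14, state_dependence_factor = 100),
    pam = modulator_spec("P", "PAM", k_on = 1, k_off_reference = 2,
                         gating_factor = 2.5, state_dependence_factor = 100)
  )
  args[names(list(...))] <- list(...)
  do.call(receptor_scheme, args)
}

#' @export
print.receptor_scheme <- function(x, ...) {
  cat(sprintf("Receptor scheme (%s): %d base states x %d layers = %d states\n",
              x$topology, length(x$base_states), length(x$layers),
              length(x$states)))
  cat("  base chain:", paste(x$base_states, collapse = " <-> "), "\n")
  if (x$gating) {
    cat(sprintf("  agonist k_on %.4g /(uM s), k_off %.4g /s; beta %.4g /s, alpha %.4g /s (E = %.3g)\n",
                x$agonist_on, x$agonist_off, x$beta, x$alpha, x$beta / x$alpha))
  } else {
    cat(sprintf("  binding-only chain, agonist k_on %.4g /(uM s), k_off %.4g /s\n",
                x$agonist_on, x$agonist_off))
  }
  for (m in x$modulators) {
    cat(sprintf("  modulator %s (%s): K_ref %.4g uM, gating factor %.4g\n",
                m$name, m$role, m$k_off_reference / m$k_on, m$gating_factor))
  }
  invisible(x)
}

# per-base-state modulator dissociation rate derived from cycle closure
.mod_koff_by_base <- function(scheme, mod) {
  nb <- length(scheme$base_states)
  out <- rep(mod$state_dependence_factor * mod$k_off_reference, nb)
  full_idx <- scheme$n_agonist_sites + 1L   # fully agonist-bound closed
  if (scheme$n_agonist_sites == 0) full_idx <- 1L
  out[full_idx] <- mod$k_off_reference
  if (scheme$gating) out[nb] <- mod$k_off_reference / mod$gating_factor
  out
}

#' Assemble the generator (Q) matrix at given ligand concentrations
#'
#' Builds the continuous-time Markov generator for the expanded state graph
#' of `scheme` at the supplied agonist, PAM and NAM concentrations.
#' Association entries are concentration-scaled (`rate * concentration`);
#' rows sum to zero; off-diagonal entries are non-negative.
#'
#' @param scheme A [receptor_scheme()].
#' @param agonist_conc,pam_conc,nam_conc Concentrations in uM, `>= 0`.
#' @return An object of class `"q_matrix"`: the generator matrix with
#'   `dimnames` equal to the expanded state labels and attribute
#'   `ligand_context`.
#' @export
build_q_matrix <- function(scheme, agonist_conc, pam_conc = 0, nam_conc = 0) {
  stopifnot(inherits(scheme, "receptor_scheme"))
  conc <- c(agonist = agonist_conc, pam = pam_conc, nam = nam_conc)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("build_q_matrix: concentrations must be finite and >= 0", call. = FALSE)
  }
  mod_conc <- vapply(scheme$modulators, function(m) {
    if (m$role == "PAM") pam_conc else nam_conc
  }, numeric(1))

  nb <- length(scheme$base_states)
  nl <- length(scheme$layers)
  n <- nb * nl
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  idx <- function(layer_i, base_i) (layer_i - 1L) * nb + base_i

  for (li in seq_len(nl)) {
    layer <- scheme$layers[[li]]
    gate_mult <- 1
    sdf_mult <- 1
    for (nm in layer) {
      gate_mult <- gate_mult * scheme$modulators[[nm]]$gating_factor
      sdf_mult <- sdf_mult * scheme$modulators[[nm]]$state_dependence_factor
    }
    # agonist binding chain within the layer
    if (scheme$n_agonist_sites > 0) {
      for (s in seq_len(scheme$n_agonist_sites)) {
        on_mult <- scheme$statistical_factors[s]
        off_mult <- scheme$statistical_factors[scheme$n_agonist_sites - s + 1L]
        koff <- scheme$agonist_off
        # cycle closure: the final agonist step is tightened by the
        # state-dependence factor of each bound modulator
        if (s == scheme$n_agonist_sites) koff <- koff / sdf_mult
        Q[idx(li, s), idx(li, s + 1L)] <- on_mult * scheme$agonist_on * agonist_conc
        Q[idx(li, s + 1L), idx(li, s)] <- off_mult * koff
      }
    }
    # gating step
    if (scheme$gating) {
      cl <- scheme$n_agonist_sites + 1L
      op <- nb
      Q[idx(li, cl), idx(li, op)] <- scheme$beta * gate_mult
      Q[idx(li, op), idx(li, cl)] <- scheme$alpha
    }
    # modulator binding/unbinding out of this layer
    for (nm in names(scheme$modulators)) {
      if (nm %in% layer) next
      target <- union(layer, nm)
      ti <- which(vapply(scheme$layers, function(l) setequal(l, target),
                         logical(1)))
      if (!length(ti)) next   # MODEL1: no doubly occupied layer
      m <- scheme$modulators[[nm]]
      koff_base <- .mod_koff_by_base(scheme, m)
      for (b in seq_len(nb)) {
        Q[idx(li, b), idx(ti, b)] <- m$k_on * mod_conc[[nm]]
        Q[idx(ti, b), idx(li, b)] <- koff_base[b]
      }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("q_matrix", "matrix", "array"),
            ligand_context = c(agonist = agonist_conc, pam = pam_conc,
                               nam = nam_conc))
}

#' Check microscopic reversibility of a scheme
#'
#' Computes spanning-tree state potentials at reference concentrations
#' (all ligands 1 uM, so every edge is active) and verifies detailed balance
#' `w_i q_ij = w_j q_ji` on every edge. For a connected reversible graph this
#' is equivalent to requiring that the product of rates clockwise equals the
#' product counter-clockwise around every cycle.
#'
#' @param scheme A [receptor_scheme()].
#' @param rtol Relative tolerance on the edge imbalance (default `1e-9`).
#' @return List with `reversible` (logical) and `max_imbalance`.
#' @export
check_reversibility <- function(scheme, rtol = 1e-9) {
  Q <- build_q_matrix(scheme, agonist_conc = 1, pam_conc = 1, nam_conc = 1)
  n <- nrow(Q)
  logw <- rep(NA_real_, n)
  logw[1] <- 0
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nbrs <- which(Q[i, ] > 0 & seq_len(n) != i)
    for (j in nbrs) {
      if (is.na(logw[j])) {
        if (Q[j, i] <= 0) {
          stop("check_reversibility: one-way edge ", rownames(Q)[i], " -> ",
               colnames(Q)[j], call. = FALSE)
        }
        logw[j] <- logw[i] + log(Q[i, j]) - log(Q[j, i])
        queue <- c(queue, j)
      }
    }
  }
  if (anyNA(logw)) {
    stop("check_reversibility: state graph is disconnected", call. = FALSE)
  }
  w <- exp(logw - max(logw))
  imb <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && Q[i, j] > 0) {
        f <- w[i] * Q[i, j]
        b <- w[j] * Q[j, i]
        imb <- max(imb, abs(f - b) / max(f, b))
      }
    }
  }
  list(reversible = imb <= rtol, max_imbalance = imb)
}

#' Equilibrium occupancy by direct linear algebra
#'
#' Solves the stationary condition `pi Q = 0` with `sum(pi) = 1` by least
#' squares on the augmented system. This is the algebraic cross-check for the
#' ODE relaxation route ([solve_equilibrium_ode()]).
#'
#' @param q A `"q_matrix"` from [build_q_matrix()].
#' @return Named numeric vector of equilibrium state probabilities (class
#'   `"occupancy"`), non-negative, summing to 1.
#' @export
solve_equilibrium_nullspace <- function(q) {
  stopifnot(is.matrix(q))
  n <- nrow(q)
  A <- rbind(t(unclass(q)), rep(1, n))
  qr_A <- qr(A)
  if (qr_A$rank < n) {
    stop("solve_equilibrium_nullspace: generator is rank deficient beyond one ",
         "(disconnected state graph?)", call. = FALSE)
  }
  pi_hat <- qr.solve(A, c(rep(0, n), 1))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0)) {
    stop("solve_equilibrium_nullspace: negative stationary probability",
         call. = FALSE)
  }
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- rownames(q)
  structure(pi_hat, class = "occupancy")
}

#' Equilibrium occupancy by ODE relaxation
#'
#' Integrates the master equation `d pi / dt = pi Q` with a stiff-capable
#' solver (`deSolve::ode`, method `lsoda`) from `initial` until the max-norm
#' of the derivative falls below `tol`, mirroring the practice of running a
#' macroscopic receptor model to steady state.
#'
#' @param q A `"q_matrix"`.
#' @param initial Initial probability vector (defaults to all mass in the
#'   first state). Must be non-negative and sum to 1.
#' @param tol Convergence tolerance on `max |d pi / dt|` (1/s).
#' @param horizon Maximum model time to integrate, s.
#' @return Named `"occupancy"` vector.
#' @export
solve_equilibrium_ode <- function(q, initial = NULL, tol = 1e-10,
                                  horizon = 1e4) {
  stopifnot(is.matrix(q))
  n <- nrow(q)
  if (is.null(initial)) initial <- c(1, rep(0, n - 1L))
  if (length(initial) != n || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8) {
    stop("solve_equilibrium_ode: initial must be a probability vector over ",
         n, " states", call. = FALSE)
  }
  if (!is.numeric(tol) || tol <= 0) {
    stop("solve_equilibrium_ode: tol must be > 0", call. = FALSE)
  }
  Qm <- unclass(q)
  deriv <- function(t, y, parms) list(as.vector(y %*% Qm))
  y <- initial / sum(initial)
  t_end <- 1
  repeat {
    # convergence is certified by the residual check below, so a chunk that
    # stops short of t_end (stiff step-limit) is re-integrated, not an error
    sol <- suppressWarnings(
      deSolve::ode(y = y, times = c(0, t_end), func = deriv,
                   parms = NULL, method = "lsoda",
                   rtol = 1e-10, atol = 1e-12, maxsteps = 5e5))
    y <- sol[nrow(sol), -1L]
    resid <- max(abs(as.vector(y %*% Qm)))
    if (resid < tol) break
    if (t_end >= horizon) {
      stop("solve_equilibrium_ode: failed to reach tolerance ", tol,
           " within horizon ", horizon, " s (residual ", format(resid), ")",
           call. = FALSE)
    }
    t_end <- min(horizon, t_end * 10)
  }
  y[y < 0 & y > -1e-12] <- 0
  y <- y / sum(y)
  names(y) <- rownames(q)
  structure(y, class = "occupancy")
}

#' Map equilibrium occupancy to a macroscopic response
#'
#' The macroscopic response is the occupancy-weighted sum over conducting
#' states. By default every expanded state whose base state is open carries
#' unit weight; custom weights allow, e.g., reading out modulator-bound
#' fraction for binding-only schemes, or unequal conductances.
#'
#' @param occ An `"occupancy"` vector.
#' @param scheme The [receptor_scheme()] the occupancy came from.
#' @param weights Optional named numeric vector of per-state weights
#'   (names are expanded state labels); unnamed states get weight 0.
#' @return A single numeric response value.
#' @export
response_readout <- function(occ, scheme, weights = NULL) {
  stopifnot(inherits(scheme, "receptor_scheme"))
  if (is.null(weights)) {
    if (!length(scheme$open_states)) {
      stop("response_readout: scheme has no open states; supply weights",
           call. = FALSE)
    }
    base_of <- rep(scheme$base_states, times = length(scheme$layers))
    w <- as.numeric(base_of %in% scheme$open_states)
    names(w) <- scheme$states
  } else {
    w <- rep(0, length(scheme$states))
    names(w) <- scheme$states
    bad <- setdiff(names(weights), scheme$states)
    if (length(bad)) {
      stop("response_readout: unknown states in weights: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    w[names(weights)] <- weights
  }
  sum(w[names(occ)] * as.numeric(occ))
}

#' Equilibrium response at given ligand concentrations
#'
#' Convenience wrapper: builds the Q matrix, solves the stationary
#' distribution algebraically and applies [response_readout()].
#'
#' @inheritParams build_q_matrix
#' @param weights Optional readout weights, see [response_readout()].
#' @return Numeric response.
#' @export
equilibrium_response <- function(scheme, agonist_conc, pam_conc = 0,
                                 nam_conc = 0, weights = NULL) {
  q <- build_q_matrix(scheme, agonist_conc, pam_conc, nam_conc)
  response_readout(solve_equilibrium_nullspace(q), scheme, weights)
}

#' Simulate a concentration-jump relaxation experiment
#'
#' Propagates state occupancy piecewise through a schedule of solution
#' exchanges (each segment holds fixed ligand concentrations), sampling the
#' macroscopic response at the requested times. The initial occupancy is the
#' equilibrium of the first segment unless given.
#'
#' @param scheme A [receptor_scheme()].
#' @param protocol A data frame with columns `start` (s, first must be 0),
#'   `agonist`, `pam`, `nam` (uM): one row per segment, in time order.
#' @param times Strictly increasing sample times (s) within the protocol span.
#' @param initial Optional starting occupancy (defaults to equilibrium of
#'   segment 1).
#' @param weights Optional readout weights.
#' @return A data frame of class `"relaxation_trace"` with columns `time`,
#'   `response` and `segment`; the protocol is kept as an attribute.
#' @export
simulate_relaxation <- function(scheme, protocol, times, initial = NULL,
                                weights = NULL) {
  stopifnot(inherits(scheme, "receptor_scheme"))
  if (!is.data.frame(protocol) || nrow(protocol) == 0) {
    stop("simulate_relaxation: empty protocol", call. = FALSE)
  }
  need <- c("start", "agonist", "pam", "nam")
  if (!all(need %in% names(protocol))) {
    stop("simulate_relaxation: protocol needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(protocol$start, strictly = TRUE)) {
    stop("simulate_relaxation: protocol segments must be ordered", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("simulate_relaxation: times must be strictly increasing", call. = FALSE)
  }
  if (min(times) < protocol$start[1]) {
    stop("simulate_relaxation: times must lie within the protocol span",
         call. = FALSE)
  }
  qs <- lapply(seq_len(nrow(protocol)), function(i) {
    build_q_matrix(scheme, protocol$agonist[i], protocol$pam[i],
                   protocol$nam[i])
  })
  if (is.null(initial)) {
    occ <- as.numeric(solve_equilibrium_nullspace(qs[[1]]))
  } else {
    occ <- as.numeric(initial)
  }
  seg_end <- c(protocol$start[-1L], max(times))
  out_t <- numeric(0); out_r <- numeric(0); out_s <- integer(0)
  for (i in seq_len(nrow(protocol))) {
    Qm <- unclass(qs[[i]])
    deriv <- function(t, y, parms) list(as.vector(y %*% Qm))
    t0 <- protocol$start[i]; t1 <- seg_end[i]
    ts <- times[times >= t0 & times <= t1]
    # drop a sample that coincides with the next segment start; it belongs
    # to the pre-switch segment only if it is the final segment
    if (i < nrow(protocol)) ts <- ts[ts < t1]
    solve_times <- sort(unique(c(t0, ts, t1)))
    if (length(solve_times) > 1) {
      sol <- deSolve::ode(y = occ, times = solve_times, func = deriv,
                          parms = NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-12)
      if (length(ts)) {
        rows <- match(ts, sol[, 1L])
        resp <- apply(sol[rows, -1L, drop = FALSE], 1L, function(y) {
          response_readout(structure(y, names = scheme$states,
                                     class = "occupancy"), scheme, weights)
        })
        out_t <- c(out_t, ts); out_r <- c(out_r, resp)
        out_s <- c(out_s, rep.int(i, length(ts)))
      }
      occ <- sol[nrow(sol), -1L]
    }
  }
  trace <- data.frame(time = out_t, response = out_r, segment = out_s)
  attr(trace, "protocol") <- protocol
  class(trace) <- c("relaxation_trace", "data.frame")
  trace
}

#' @export
print.occupancy <- function(x, ...) {
  cat("Equilibrium state occupancy (sum =", format(sum(x)), "):\n")
  print(round(unclass(x), 6))
  invisible(x)
}
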