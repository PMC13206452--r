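# Assembly of the reduced whole-body flow-limited model and its ODE
# right-hand side.  Compartments per drug: gut lumen, gut tissue, portal
# vein, liver, kidney, arterial plasma, venous plasma, lumped rest-of-body,
# plus urine, feces and metabolized sinks.  Transporter-mediated efflux
# couples gut tissue back to the lumen (-> feces on transit) and kidney to
# the urine sink.  A perpetrator drug is co-integrated and acts on the
# victim only through expression states (induction turnover, static fold)
# and apparent-Km scaling (competitive inhibition).

N_COMP <- 11L
COMP_NAMES <- c("lumen", "gut", "portal", "liver", "kidney", "art", "ven",
                "rest", "urine", "feces", "metabolized")

#' Michaelis-Menten transporter flux
#'
#' `flux = Kcat x E x S / (Km_app + S)` where `E` is the transporter amount
#' available in the organ (baseline amount times the dynamic expression
#' state).  Saturates at `Kcat x E` for large substrate concentrations and
#' is linear (`Kcat x E x S / Km_app`) at low concentrations; zero
#' expression yields zero flux.
#'
#' @param substrate_free_conc unbound substrate concentration, umol/L
#' @param kinetics a [transporter_kinetics()] object
#' @param expression_state expression as a fraction of baseline, >= 0
#' @param transporter_amount baseline transporter amount in the organ, pmol
#'   scale consistent with `kcat` (reference concentration x relative
#'   expression x organ volume)
#' @param km_app apparent Michaelis constant, umol/L (defaults to the
#'   uninhibited Km)
#' @return flux in umol/min
#' @export
transporter_flux <- function(substrate_free_conc, kinetics,
                             expression_state = 1, transporter_amount,
                             km_app = kinetics$km) {
  stopifnot(inherits(kinetics, "pbpk_transporter"))
  if (any(km_app <= 0)) stop("km_app must be > 0", call. = FALSE)
  if (any(expression_state < 0))
    stop("expression_state must be >= 0", call. = FALSE)
  s <- pmax(substrate_free_conc, 0)
  kinetics$kcat * transporter_amount * expression_state * s / (km_app + s)
}

#' Baseline transporter amount in an organ
#'
#' Reference concentration x relative organ expression x organ volume.
#'
#' @param kinetics a [transporter_kinetics()] object
#' @param physiology a `pbpk_physiology`
#' @param organ organ name (`"gut"`, `"kidney"`, `"liver"`)
#' @return transporter amount on the umol scale used by `kcat`
#' @export
organ_transporter_amount <- function(kinetics, physiology, organ) {
  kinetics$reference_concentration *
    relative_expression(physiology, organ, kinetics$transporter_id) *
    physiology$volumes[[organ]]
}

default_mechanism_flags <- function() {
  list(abcb1_induction = TRUE, abcb1_inhibition = TRUE,
       abcg2_inhibition = TRUE, abcg2_static_fold = TRUE)
}

mechanism_enabled <- function(flags, target, mechanism) {
  key <- paste0(tolower(target), "_",
                switch(mechanism,
                       induction = "induction",
                       competitive_inhibition = "inhibition",
                       static_fold = "static_fold"))
  if (is.null(flags[[key]])) TRUE else isTRUE(flags[[key]])
}

# organ housing each transporter's local perpetrator concentration
EFFLUX_DEST <- c(gut = "lumen", kidney = "urine", liver = "feces")

#' Build a whole-body PBPK model
#'
#' Assembles state indexing, flow constants, partition coefficients,
#' transporter flux entries and induction turnover states for a victim
#' (and optional co-integrated perpetrator), and returns the ODE
#' right-hand side together with the bookkeeping needed by the simulation
#' driver.
#'
#' @param victim victim [compound_model()]
#' @param physiology a `pbpk_physiology`
#' @param perpetrator optional perpetrator [compound_model()]
#' @param mechanism_flags named list of logicals switching individual
#'   victim-directed interaction mechanisms (`abcb1_induction`,
#'   `abcb1_inhibition`, `abcg2_inhibition`, `abcg2_static_fold`); unnamed
#'   mechanisms default to enabled
#' @param victim_multiple_dose use the multiple-dose hepatic clearance for
#'   the victim
#' @param perpetrator_start_min time of the first perpetrator dose (static
#'   folds and, for bookkeeping, co-administration start)
#' @param kdeg transporter degradation rate constant for induction
#'   turnover, 1/min (default half-life 36 h)
#' @return an object of class `pbpk_model` with elements `rhs` (function
#'   `(t, y, parms)` for deSolve), `n_states`, `state_names`, `drugs`,
#'   `expression_names`, and internal index tables
#' @export
build_pbpk_model <- function(victim, physiology, perpetrator = NULL,
                             mechanism_flags = default_mechanism_flags(),
                             victim_multiple_dose = FALSE,
                             perpetrator_start_min = 0,
                             kdeg = log(2) / 2160) {
  validate_physiology(physiology)
  drugs <- list(victim = victim)
  if (!is.null(perpetrator)) drugs$perpetrator <- perpetrator
  nd <- length(drugs)
  v <- physiology$volumes
  q <- physiology$flows
  Qg <- q[["gut"]]; Qha <- q[["hepatic_artery"]]
  Qk <- q[["kidney"]]; Qr <- q[["rest"]]
  Qliv <- Qg + Qha
  Qco <- physiology$cardiac_output_plasma
  ktr <- 1 / physiology$gut_transit_time

  # per-drug constants -------------------------------------------------------
  off <- (seq_len(nd) - 1L) * N_COMP
  dp <- vector("list", nd)
  state_names <- character(0)
  for (i in seq_len(nd)) {
    cmp <- drugs[[i]]
    kp <- compound_partitions(cmp, physiology)
    multiple <- if (i == 1L) victim_multiple_dose else TRUE
    # conc divisors (plasma-referenced) for gut, portal, liver, kidney,
    # art, ven, rest in state order 2..8
    div <- c(v[["gut"]] * kp[["gut"]], v[["portal"]],
             v[["liver"]] * kp[["liver"]], v[["kidney"]] * kp[["kidney"]],
             v[["art"]], v[["ven"]], v[["rest"]] * kp[["rest"]])
    dp[[i]] <- list(
      off = off[i],
      fu = cmp$physchem$fu_plasma,
      mw = cmp$physchem$molecular_weight,
      ka = if (is.finite(cmp$intestinal_permeability))
             absorption_rate_constant(cmp, physiology) else 0,
      div = div,
      cl_h = hepatic_cl_Lmin(cmp, physiology$body_weight, multiple),
      gfr_cl = cmp$clearance$gfr_fraction * physiology$gfr *
        cmp$physchem$fu_plasma,
      kp = kp)
    state_names <- c(state_names,
                     paste(names(drugs)[i], COMP_NAMES, sep = "."))
  }

  # organ state index helper (1-based within full state vector)
  oidx <- function(drug_i, comp) off[drug_i] + match(comp, COMP_NAMES)

  # perpetrator-driven machinery ---------------------------------------------
  has_perp <- nd == 2L
  perp <- if (has_perp) drugs$perpetrator else NULL
  fu_p <- if (has_perp) perp$physchem$fu_plasma else 0
  perp_div <- if (has_perp) dp[[2]]$div else rep(1, 7)
  local_perp_idx <- function(organ) {
    # organ housing the transporter: gut tissue for intestinal, kidney for
    # renal, liver for hepatic transporters/enzymes
    oidx(2L, organ)
  }
  local_perp_div <- function(organ) {
    perp_div[match(organ, COMP_NAMES[2:8])]
  }

  # induction turnover states: one per (victim-directed induction entry x
  # organ with victim expression) plus perpetrator self-clearance entries
  expr_names <- character(0)
  ex <- list(kdeg = numeric(0), emax = numeric(0), ec50 = numeric(0),
             drv_idx = integer(0), drv_div = numeric(0))
  expr_key <- character(0)   # "organ.transporter" lookup for flux entries
  self_frac <- numeric(0)    # perpetrator self-clearance fractions
  self_idx <- integer(0)
  n_expr <- 0L
  if (has_perp) {
    for (e in interaction_entries(perp, "victim", "induction")) {
      if (!mechanism_enabled(mechanism_flags, e$target, "induction")) next
      for (organ in c("gut", "kidney", "liver")) {
        if (relative_expression(physiology, organ, e$target) <= 0) next
        if (!e$target %in% names(drugs$victim$transporters)) next
        n_expr <- n_expr + 1L
        ex$kdeg <- c(ex$kdeg, kdeg)
        ex$emax <- c(ex$emax, e$emax)
        ex$ec50 <- c(ex$ec50, e$ec50)
        ex$drv_idx <- c(ex$drv_idx, local_perp_idx(organ))
        ex$drv_div <- c(ex$drv_div, local_perp_div(organ))
        expr_key <- c(expr_key, paste(organ, e$target, sep = "."))
        expr_names <- c(expr_names, paste0("E.", organ, ".", e$target))
      }
    }
    for (e in interaction_entries(perp, "self_clearance", "induction")) {
      n_expr <- n_expr + 1L
      ex$kdeg <- c(ex$kdeg, kdeg)
      ex$emax <- c(ex$emax, e$emax)
      ex$ec50 <- c(ex$ec50, e$ec50)
      ex$drv_idx <- c(ex$drv_idx, local_perp_idx("liver"))
      ex$drv_div <- c(ex$drv_div, local_perp_div("liver"))
      expr_key <- c(expr_key, paste0("self.", e$target))
      expr_names <- c(expr_names, paste0("E.self.", e$target))
      self_frac <- c(self_frac, e$clearance_fraction)
      self_idx <- c(self_idx, nd * N_COMP + n_expr)
    }
  }
  ex_idx <- nd * N_COMP + seq_len(n_expr)
  ex$drv_idx <- as.integer(ex$drv_idx)
  # uninduced fraction of perpetrator clearance stays constant
  self_base <- if (length(self_frac)) 1 - sum(self_frac) else 1
  if (self_base < -1e-9)
    stop("self-clearance fractions exceed 1", call. = FALSE)

  # transporter flux entries (victim; perpetrator transporters would be
  # handled identically if present) -----------------------------------------
  fe <- list(src = integer(0), dst = integer(0), div = numeric(0),
             vmax0 = numeric(0), km = numeric(0), fu = numeric(0),
             ki = numeric(0), inh_idx = integer(0), inh_div = numeric(0),
             inh_fu = numeric(0), expr_idx = integer(0), fold = numeric(0))
  for (i in seq_len(nd)) {
    cmp <- drugs[[i]]
    for (tr in cmp$transporters) {
      for (organ in c("gut", "kidney", "liver")) {
        amount <- organ_transporter_amount(tr, physiology, organ)
        if (amount <= 0) next
        # perpetrator effects only act on the victim
        inh <- NULL; fold <- 1; eix <- 0L
        if (has_perp && i == 1L) {
          inh_entries <- interaction_entries(perp, "victim",
                                             "competitive_inhibition",
                                             tr$transporter_id)
          if (length(inh_entries) &&
              mechanism_enabled(mechanism_flags, tr$transporter_id,
                                "competitive_inhibition"))
            inh <- inh_entries[[1]]
          fold_entries <- interaction_entries(perp, "victim", "static_fold",
                                              tr$transporter_id)
          if (length(fold_entries) &&
              mechanism_enabled(mechanism_flags, tr$transporter_id,
                                "static_fold"))
            fold <- fold_entries[[1]]$fold
          key <- paste(organ, tr$transporter_id, sep = ".")
          hit <- match(key, expr_key)
          if (!is.na(hit)) eix <- ex_idx[hit]
        }
        fe$src <- c(fe$src, oidx(i, organ))
        fe$dst <- c(fe$dst, oidx(i, EFFLUX_DEST[[organ]]))
        fe$div <- c(fe$div, dp[[i]]$div[match(organ, COMP_NAMES[2:8])])
        fe$vmax0 <- c(fe$vmax0, tr$kcat * amount)
        fe$km <- c(fe$km, tr$km)
        fe$fu <- c(fe$fu, cmp$physchem$fu_plasma)
        fe$ki <- c(fe$ki, if (is.null(inh)) Inf else inh$ki)
        fe$inh_idx <- c(fe$inh_idx,
                        if (is.null(inh)) 1L else local_perp_idx(organ))
        fe$inh_div <- c(fe$inh_div,
                        if (is.null(inh)) 1 else local_perp_div(organ))
        fe$inh_fu <- c(fe$inh_fu, if (is.null(inh)) 0 else fu_p)
        fe$expr_idx <- c(fe$expr_idx, as.integer(eix))
        fe$fold <- c(fe$fold, fold)
      }
    }
  }
  n_flux <- length(fe$src)
  fold_start <- perpetrator_start_min

  n_states <- nd * N_COMP + n_expr
  state_names <- c(state_names, expr_names)
  y0 <- setNames(numeric(n_states), state_names)
  if (n_expr) y0[ex_idx] <- 1

  V_pv <- v[["portal"]]; V_a <- v[["art"]]; V_v <- v[["ven"]]

  rhs <- function(t, y, parms) {
    if (any(y[seq_len(nd * N_COMP)] < -1e-6))
      stop("negative compartment amount: solver misconfiguration",
           call. = FALSE)
    dy <- numeric(n_states)

    # transporter fluxes -----------------------------------------------------
    if (n_flux) {
      s <- fe$fu * pmax(y[fe$src], 0) / fe$div
      conc_i <- fe$inh_fu * pmax(y[fe$inh_idx], 0) / fe$inh_div
      km_app <- fe$km * (1 + conc_i / fe$ki)
      e_mult <- rep(1, n_flux)
      hasx <- fe$expr_idx > 0L
      if (any(hasx)) e_mult[hasx] <- pmax(y[fe$expr_idx[hasx]], 0)
      if (t >= fold_start) e_mult <- e_mult * fe$fold
      flux <- fe$vmax0 * e_mult * s / (km_app + s)
      for (j in seq_len(n_flux)) {
        dy[fe$src[j]] <- dy[fe$src[j]] - flux[j]
        dy[fe$dst[j]] <- dy[fe$dst[j]] + flux[j]
      }
    }

    # per-drug flow and elimination balance ----------------------------------
    for (i in seq_len(nd)) {
      p <- dp[[i]]
      o <- p$off
      cg <- y[o + 2L] / p$div[1]; cpv <- y[o + 3L] / p$div[2]
      cli <- y[o + 4L] / p$div[3]; ck <- y[o + 5L] / p$div[4]
      ca <- y[o + 6L] / p$div[5]; cv <- y[o + 7L] / p$div[6]
      cr <- y[o + 8L] / p$div[7]
      cl_h <- p$cl_h
      if (i == 2L && length(self_idx))
        cl_h <- cl_h * (self_base + sum(self_frac * y[self_idx]))
      abs_rate <- p$ka * y[o + 1L]
      transit <- ktr * y[o + 1L]
      filt <- p$gfr_cl * ca
      met <- cl_h * cli
      dy[o + 1L] <- dy[o + 1L] - abs_rate - transit
      dy[o + 2L] <- dy[o + 2L] + abs_rate + Qg * (ca - cg)
      dy[o + 3L] <- dy[o + 3L] + Qg * (cg - cpv)
      dy[o + 4L] <- dy[o + 4L] + Qg * cpv + Qha * ca - Qliv * cli - met
      dy[o + 5L] <- dy[o + 5L] + Qk * (ca - ck) - filt
      dy[o + 6L] <- dy[o + 6L] + Qco * cv - (Qg + Qha + Qk + Qr) * ca
      dy[o + 7L] <- dy[o + 7L] + Qliv * cli + Qk * ck + Qr * cr -
        Qco * cv + parms[i]
      dy[o + 8L] <- dy[o + 8L] + Qr * (ca - cr)
      dy[o + 9L] <- dy[o + 9L] + filt
      dy[o + 10L] <- dy[o + 10L] + transit
      dy[o + 11L] <- dy[o + 11L] + met
    }

    # induction turnover -----------------------------------------------------
    if (n_expr) {
      conc_i <- fu_p * pmax(y[ex$drv_idx], 0) / ex$drv_div
      dy[ex_idx] <- ex$kdeg *
        (1 + ex$emax * conc_i / (ex$ec50 + conc_i) - y[ex_idx])
    }
    list(dy)
  }

  structure(
    list(rhs = rhs, n_states = n_states, state_names = state_names,
         n_drugs = nd, drug_names = names(drugs), drugs = drugs,
         y0 = y0, offsets = off, physiology = physiology,
         partitions = lapply(dp, `[[`, "kp"),
         dp = dp, flux_entries = fe, expression_names = expr_names,
         expression_idx = ex_idx, mechanism_flags = mechanism_flags,
         perpetrator_start_min = perpetrator_start_min),
    class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model>", paste(x$drug_names, collapse = " + "), "\n")
  cat(sprintf("  %d states (%d compartments x %d drugs + %d expression)\n",
              x$n_states, N_COMP, x$n_drugs,
              length(x$expression_names)))
  invisible(x)
}
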