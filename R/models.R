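#' Catalog of the nine two-population divergence models
#'
#' Two families of diffusion models of divergence from a common ancestral
#' population of relative size 1 (sizes in units of `N_ref`, times in
#' `2 N_ref` generations, migration as `2 N_ref m`):
#'
#' * **Vicariance** -- the ancestor splits into fractions `s` (population 1)
#'   and `1 - s` (population 2) which keep those sizes: `vic_no_mig`,
#'   `vic_anc_sym_mig` (symmetric migration `M` for `T1`, then isolation for
#'   `T2`), `vic_sec_contact_sym_mig` (isolation for `T1`, then symmetric
#'   migration for `T2`).
#' * **Founder event** -- population 1 is the source and keeps size `1 - s`;
#'   population 2 is founded at fraction `s` and grows exponentially to
#'   `nu2` over the total divergence time (growth spans both epochs in
#'   two-epoch models): `founder_nomig`, `founder_sym`, `founder_asym`,
#'   `founder_anc_sym_mig`, `founder_sec_contact_sym`,
#'   `founder_sec_contact_asym`.
#'
#' @return Named list of model specifications: `name`, `family`, `params`
#'   (ordered free-parameter names; the count is the `k` used by AIC).
#' @export
model_catalog <- function() {
  spec <- list(
    vic_no_mig = c("s", "T"),
    vic_anc_sym_mig = c("s", "M", "T1", "T2"),
    vic_sec_contact_sym_mig = c("s", "M", "T1", "T2"),
    founder_nomig = c("s", "nu2", "T"),
    founder_sym = c("s", "nu2", "M", "T"),
    founder_asym = c("s", "nu2", "M12", "M21", "T"),
    founder_anc_sym_mig = c("s", "nu2", "M", "T1", "T2"),
    founder_sec_contact_sym = c("s", "nu2", "M", "T1", "T2"),
    founder_sec_contact_asym = c("s", "nu2", "M12", "M21", "T1", "T2")
  )
  lapply(stats::setNames(names(spec), names(spec)), function(nm) {
    list(name = nm,
         family = if (startsWith(nm, "vic")) "vicariance" else "founder",
         params = spec[[nm]])
  })
}

get_model <- function(model) {
  if (is.list(model) && !is.null(model$name)) model <- model$name
  cat <- model_catalog()
  if (!model %in% names(cat)) {
    stop(sprintf("unknown model '%s'; see model_catalog()", model))
  }
  cat[[model]]
}

check_params <- function(model, p) {
  model <- get_model(model)
  p <- unlist(p)
  if (!all(model$params %in% names(p))) {
    stop(sprintf("model %s needs parameters: %s", model$name,
                 paste(model$params, collapse = ", ")))
  }
  p <- p[model$params]
  if (!is.null(p["s"]) && (p[["s"]] <= 0 || p[["s"]] >= 1)) {
    stop("s must be in (0, 1)")
  }
  sizes <- p[names(p) %in% "nu2"]
  if (any(sizes <= 0)) stop("sizes must be > 0")
  if (any(p[grepl("^M", names(p))] < 0)) stop("migration rates must be >= 0")
  if (any(p[grepl("^T", names(p))] < 0)) stop("times must be >= 0")
  p
}

#' Epoch table for a model at given parameters
#'
#' Expands a catalog model into forward-time epochs, each with a duration,
#' start/end relative sizes of the two populations (exponentially
#' interpolated within the epoch), and per-epoch migration rates. This is
#' the single description consumed by both the diffusion engine and the
#' coalescent simulator.
#'
#' @param model catalog model name (or entry).
#' @param params named numeric vector of the model's parameters.
#' @return data.frame with columns `dur, nu1_0, nu1_1, nu2_0, nu2_1, m12, m21`.
#' @export
model_epochs <- function(model, params) {
  model <- get_model(model)
  p <- as.list(check_params(model, params))
  ep <- function(dur, nu1_0, nu1_1, nu2_0, nu2_1, m12, m21) {
    data.frame(dur = dur, nu1_0 = nu1_0, nu1_1 = nu1_1,
               nu2_0 = nu2_0, nu2_1 = nu2_1, m12 = m12, m21 = m21)
  }
  out <- switch(model$name,
    vic_no_mig = ep(p$T, p$s, p$s, 1 - p$s, 1 - p$s, 0, 0),
    vic_anc_sym_mig = rbind(
      ep(p$T1, p$s, p$s, 1 - p$s, 1 - p$s, p$M, p$M),
      ep(p$T2, p$s, p$s, 1 - p$s, 1 - p$s, 0, 0)),
    vic_sec_contact_sym_mig = rbind(
      ep(p$T1, p$s, p$s, 1 - p$s, 1 - p$s, 0, 0),
      ep(p$T2, p$s, p$s, 1 - p$s, 1 - p$s, p$M, p$M)),
    founder_nomig = ep(p$T, 1 - p$s, 1 - p$s, p$s, p$nu2, 0, 0),
    founder_sym = ep(p$T, 1 - p$s, 1 - p$s, p$s, p$nu2, p$M, p$M),
    founder_asym = ep(p$T, 1 - p$s, 1 - p$s, p$s, p$nu2, p$M12, p$M21),
    founder_anc_sym_mig = ,
    founder_sec_contact_sym = ,
    founder_sec_contact_asym = {
      # exponential growth of the founded deme spans T1 + T2
      Tt <- p$T1 + p$T2
      nu_mid <- if (Tt > 0) p$s * (p$nu2 / p$s)^(p$T1 / Tt) else p$nu2
      m1 <- switch(model$name, founder_anc_sym_mig = c(p$M, p$M), c(0, 0))
      m2 <- switch(model$name,
                   founder_anc_sym_mig = c(0, 0),
                   founder_sec_contact_sym = c(p$M, p$M),
                   founder_sec_contact_asym = c(p$M12, p$M21))
      rbind(ep(p$T1, 1 - p$s, 1 - p$s, p$s, nu_mid, m1[1], m1[2]),
            ep(p$T2, 1 - p$s, 1 - p$s, nu_mid, p$nu2, m2[1], m2[2]))
    }
  )
  out[out$dur > 0, , drop = FALSE]
}

#' Default optimisation bounds per parameter
#'
#' Permissive box bounds used by [optimize_fit()] unless overridden:
#' `s` in `[0.01, 0.99]`, sizes in `[1e-3, 100]`, migration in
#' `[1e-4, 20]` (log-scale search needs a positive floor), times in
#' `[1e-3, 15]`.
#'
#' @param model catalog model name.
#' @export
default_bounds <- function(model) {
  model <- get_model(model)
  lower <- upper <- stats::setNames(numeric(length(model$params)), model$params)
  for (nm in model$params) {
    b <- if (nm == "s") c(0.01, 0.99)
      else if (startsWith(nm, "nu")) c(1e-3, 100)
      else if (startsWith(nm, "M")) c(1e-4, 20)
      else c(1e-3, 15)
    lower[nm] <- b[1]
    upper[nm] <- b[2]
  }
  list(lower = lower, upper = upper)
}

# total divergence time of a parameter vector (T, or T1 + T2)
total_divergence_time <- function(model, params) {
  model <- get_model(model)
  tn <- intersect(c("T", "T1", "T2"), model$params)
  sum(unlist(params[tn]))
}
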