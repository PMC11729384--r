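# Shared fixtures: small generating configurations and the model specs used
# throughout the suite. Everything is generated in code at test time.

full_spec <- function() {
  gsem_spec(
    latents = list(screens = c("computer_smartphone", "tv", "video_games"),
                   transport = c("motor_vehicle", "cycling", "walking")),
    disease = obesity ~ sex + age + ethnicity + schooling + wealth_quartile +
      energy_kcal + leisure_pa,
    structural = ~ leisure_pa)
}

screens_spec <- function() {
  gsem_spec(latents = list(screens = c("computer_smartphone", "tv", "video_games")))
}

transport_spec <- function() {
  gsem_spec(latents = list(transport = c("motor_vehicle", "cycling", "walking")))
}

latent_free_spec <- function() {
  gsem_spec(disease = obesity ~ sex + age + ethnicity + wealth_quartile + leisure_pa)
}

# configuration with the latent dimensions switched off in the disease model,
# so the latent-free disease spec is correctly specified
latent_free_config <- function(n) {
  cf <- synthetic_config(n_persons = n)
  cf$disease_coefs[["L.screens"]] <- 0
  cf$disease_coefs[["L.transport"]] <- 0
  cf
}

# moderate-loading configuration that is comfortably identified at small n
mild_config <- function(n, ...) {
  synthetic_config(
    n_persons = n,
    latent_sds = c(screens = 0.3, transport = 0.5),
    loadings = list(
      screens = c(computer_smartphone = 1, tv = 2, video_games = -3),
      transport = c(motor_vehicle = 1, cycling = -2, walking = 0.8)),
    ...)
}

# truth vector for a spec/model in packing order, from a generating config
true_theta <- function(spec, data, config = attr(data, "config"),
                       alpha = attr(data, "alpha")) {
  st <- gsem_start(spec, data)
  th <- st
  nm <- names(st)
  for (d in names(config$loadings)) {
    for (j in names(config$loadings[[d]])) {
      th[nm == paste0(d, ".kappa.", j)] <- config$intercepts[[d]][[j]]
      th[nm == paste0(d, ".lambda.", j)] <- config$loadings[[d]][[j]]
      th[nm == paste0(d, ".logshape.", j)] <- log(config$shapes[[d]][[j]])
    }
    th[nm == paste0("gamma.", d, ".leisure_pa")] <- config$gamma[[d]]
  }
  sds <- config$latent_sds; rho <- config$latent_corr
  if (any(nm == "psi.logsd.screens")) th[nm == "psi.logsd.screens"] <- log(sds[["screens"]])
  if (any(nm == "psi.logsd.transport")) th[nm == "psi.logsd.transport"] <- log(sds[["transport"]])
  if (any(nm == "psi.logchol.screens")) {
    th[nm == "psi.logchol.screens"] <- log(sds[["screens"]])
    th[nm == "psi.chol.transport.screens"] <- sds[["transport"]] * rho
    th[nm == "psi.logchol.transport"] <- log(sds[["transport"]] * sqrt(1 - rho^2))
  }
  cfd <- config$disease_coefs
  dmap <- c("disease.sexfemale" = "sexfemale", "disease.age" = "age",
            "disease.ethnicityafro" = "ethnicityafro",
            "disease.ethnicityindigenous" = "ethnicityindigenous",
            "disease.schoolingsecondary" = "schoolingsecondary",
            "disease.schoolingtertiary" = "schoolingtertiary",
            "disease.wealth_quartileQ2" = "wealthQ2",
            "disease.wealth_quartileQ3" = "wealthQ3",
            "disease.wealth_quartileQ4" = "wealthQ4",
            "disease.energy_kcal" = "energy_kcal",
            "disease.leisure_pa" = "leisure_pa",
            "disease.L.screens" = "L.screens",
            "disease.L.transport" = "L.transport")
  for (pn in names(dmap)) if (any(nm == pn)) th[nm == pn] <- cfd[[dmap[[pn]]]]
  if (any(nm == "disease.(Intercept)") && !is.null(alpha))
    th[nm == "disease.(Intercept)"] <- alpha
  th
}

# small cached transport measurement fit used by method-surface tests
transport_fit_for_methods <- local({
  env <- new.env()
  function() {
    if (is.null(env$res)) {
      cfg <- mild_config(800, gamma = c(screens = 0, transport = 0))
      d <- generate_dataset(cfg, seed = 26)
      env$res <- list(d = d, fit = fit_gsem(transport_spec(), d, se = FALSE))
    }
    env$res
  }
})
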