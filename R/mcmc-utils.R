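# Shared JAGS driver: seeded parallel-chain sampling plus convergence
# diagnostics (split-chain R-hat via coda::gelman.diag, effective sample
# size via coda::effectiveSize).

run_jags <- function(model_string, data, monitors, chains, iter,
                     burnin_frac, thin, seed, quiet = TRUE) {
  if (chains < 1 || iter < 4) stop_bad_arg("Need chains >= 1 and iter >= 4.")
  burn <- floor(iter * burnin_frac)
  keep <- iter - burn
  if (keep < thin) stop_bad_arg("No draws retained: iter/burnin/thin mismatch.")

  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((seed + 1000L * k) %% .Machine$integer.max))
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = chains,
                             n.adapt = min(1000L, burn), quiet = quiet)
  update_quietly(model, burn, quiet)
  samples <- coda_quietly(model, monitors, keep, thin, quiet)

  draws <- do.call(rbind, lapply(samples, as.matrix))
  chain_id <- rep(seq_len(chains), each = nrow(samples[[1]]))

  rhat <- if (chains >= 2) {
    g <- try(coda::gelman.diag(samples, autoburnin = FALSE,
                               multivariate = FALSE), silent = TRUE)
    if (inherits(g, "try-error")) rep(NA_real_, ncol(draws)) else
      g$psrf[colnames(draws), 1]
  } else {
    rep(NA_real_, ncol(draws))
  }
  ess <- as.numeric(coda::effectiveSize(samples)[colnames(draws)])

  list(
    draws = draws,
    chain_id = chain_id,
    diagnostics = tibble::tibble(
      term = colnames(draws),
      rhat = unname(rhat),
      ess = ess
    )
  )
}

update_quietly <- function(model, burn, quiet) {
  if (burn <= 0) return(invisible())
  if (quiet) {
    invisible(utils::capture.output(stats::update(model, n.iter = burn,
                                                  progress.bar = "none")))
  } else {
    stats::update(model, n.iter = burn)
  }
}

coda_quietly <- function(model, monitors, keep, thin, quiet) {
  if (quiet) {
    out <- NULL
    invisible(utils::capture.output(
      out <- rjags::coda.samples(model, variable.names = monitors,
                                 n.iter = keep, thin = thin,
                                 progress.bar = "none")
    ))
    out
  } else {
    rjags::coda.samples(model, variable.names = monitors, n.iter = keep,
                        thin = thin)
  }
}

check_convergence <- function(diagnostics, threshold = 1.05) {
  bad <- diagnostics$term[!is.na(diagnostics$rhat) &
                            diagnostics$rhat > threshold]
  if (length(bad) > 0) {
    warn(paste0("MCMC convergence warning: R-hat > ", threshold, " for ",
                paste(bad, collapse = ", "),
                ". Inspect diagnostics before using this fit."),
         class = "cqrisk_convergence_warning")
    return(FALSE)
  }
  TRUE
}
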