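# Shared fixtures: a cached study-sized dataset and cheap cached fits so
# several test files can reuse the same posterior draws, plus a
# constant-draw "fit" builder for algebraic checks on derived quantities.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

paperlike_data <- function() {
  cached("data45", generate_trial(paper_like_config(), seed = 20260919))
}

# Reduced-effort fit on the study-sized dataset, cached per outcome.
quick_fit <- function(outcome) {
  cached(paste0("fit_", outcome), suppressWarnings(
    fit_model(model_spec(outcome), paperlike_data(), chains = 2L,
              iter = 1000L, warmup = 500L, substeps = 2L, seed = 101L)))
}

quick_fits_all <- function() {
  outs <- c("postIAT", "postPRCA24", "postSPIC", "afterSPIC", "postSTAI")
  stats::setNames(lapply(outs, quick_fit), outs)
}

# A fit-shaped object with caller-supplied draws (constant vectors or an
# ndraw x npar matrix), for exact algebraic checks.
fake_fit <- function(outcome, params, ndraw = 40L, n_obs = 45L) {
  spec <- model_spec(outcome)
  nm <- free_params(spec)
  if (is.matrix(params)) {
    stopifnot(setequal(colnames(params), nm))
    ndraw <- nrow(params)
    m <- params[, nm, drop = FALSE]
  } else {
    stopifnot(setequal(names(params), nm))
    m <- matrix(rep(unlist(params[nm]), each = ndraw), nrow = ndraw,
                dimnames = list(NULL, nm))
  }
  half <- ndraw %/% 2L
  draws <- array(NA_real_, dim = c(half, 2L, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  for (j in seq_along(nm)) {
    draws[, 1L, j] <- m[seq_len(half), j]
    draws[, 2L, j] <- m[(half + 1L):(2L * half), j]
  }
  structure(
    list(spec = spec, draws = draws, parameters = nm, fixed = numeric(),
         rhat = stats::setNames(rep(1, length(nm)), nm), converged = TRUE,
         accept = c(1, 1), n_obs = n_obs, n_used = n_obs,
         meta = list(chains = 2L, iter = ndraw, warmup = 0L, seed = 0L,
                     substeps = 1L)),
    class = "bancova_fit")
}
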