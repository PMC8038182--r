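expit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

# restore the caller's RNG state on exit so seeded sampling leaves no
# global side effects
with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  force(expr)
}

stop_domain <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("pedfl_domain_error", "error")))
}

is_binary01 <- function(x) all(x %in% c(0, 1))
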