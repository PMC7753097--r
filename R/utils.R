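# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  force(code)
}

# Mode of values binned to one decimal (0.1 ms bins); ties broken by the
# smallest absolute value.
binned_mode <- function(x, digits = 1) {
  stopifnot(length(x) >= 1)
  r <- round(x, digits)
  tab <- table(r)
  vals <- as.numeric(names(tab))
  top <- vals[tab == max(tab)]
  top[which.min(abs(top))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tvalpha <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tvalpha_error")))
}
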