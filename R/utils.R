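# internal helpers shared across modules

# Deterministic 31-bit stream seed derived from a master seed and a string
# key (e.g. a mouse id), so per-animal randomness is stable under cohort
# edits elsewhere.
hash_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(as.character(key))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# run a thunk under a local RNG state seeded with `seed`; the seed is forced
# first so RNG draws made while computing it are not rolled back
with_seed <- function(seed, expr) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Convert occupancy interval times (POSIXct or numeric hours) to numeric
# hours since `origin` (defaults to the earliest start).
time_to_hours <- function(t, origin = NULL) {
  if (inherits(t, "POSIXt")) {
    origin <- origin %||% min(t)
    as.numeric(difftime(t, origin, units = "hours"))
  } else {
    as.numeric(t) - (if (is.null(origin)) 0 else as.numeric(origin))
  }
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == round(x)

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}
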