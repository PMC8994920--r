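# Internal helpers: variable registries, column naming, seed streams.

# Substantive per-wave variables of the cohort layout.
.adl_items  <- paste0("adl", 1:6)
.iadl_items <- paste0("iadl", 1:6)
.item_vars  <- c(.adl_items, .iadl_items)
.outcome_vars <- c("climb", "walk")
.risk_vars  <- c("smoker", "obese", "alcohol", "hypertension", "vpa")
.score_vars <- c("adl_score", "iadl_score")
# variables blanked by wave non-response / structural missingness (not age, sex, alive)
.substantive_vars <- c(.item_vars, .outcome_vars, .risk_vars)
.id_vars <- c("id", "study", "sex", "education")

wave_col <- function(var, year) paste0(var, "_", year)

# Split "var_year" column names; returns NA year for time-independent columns.
parse_col <- function(cols) {
  m <- regmatches(cols, regexec("^(.*)_([0-9]{4})$", cols))
  var <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  year <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else NA_integer_, 1L)
  ifelse_var <- ifelse(is.na(var), cols, var)
  data.frame(col = cols, var = ifelse_var, year = year, stringsAsFactors = FALSE)
}

# Deterministic 31-bit seed stream derived from a master seed and a key path,
# so any single (module, replicate, stage) stream is independently reproducible.
derive_seed <- function(seed, ...) {
  parts <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# stable per-id fair coin (used for single-follow-up wave assignment): the
# assignment must survive re-assembly of the same table under the same seed.
id_coin <- function(ids, seed) {
  vapply(as.character(ids), function(i) derive_seed(seed, "coin", i) %% 2L, 0L,
         USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
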