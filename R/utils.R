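# Internal helpers shared across modules.

# minute of day (0..1439, possibly fractional) of a POSIXct
.minuteOfDay <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

.dateOf <- function(x) as.Date(x, tz = "UTC")

# deterministic 31-bit string hash (for per-participant seed derivation and
# config provenance); stable across platforms, independent of R's RNG
.stableHash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647L
  as.integer(h)
}

# derive a child seed < 2^31 from a base seed and a label
.deriveSeed <- function(seed, label) {
  as.integer((as.numeric(seed) * 1000003 + .stableHash(label)) %% 2147483647)
}

# short provenance hash of an arbitrary configuration object
.configHash <- function(...) {
  sprintf("%08x", .stableHash(paste(deparse(list(...)), collapse = "")))
}

# write lines/data.frame atomically: temp file in the target dir, then rename
.atomicWrite <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temporary file to ", path)
  ok <- TRUE
  invisible(path)
}

# mean of a circular quantity given in minutes on a cycle of `period`
.circularMeanMinutes <- function(m, period = 1440) {
  ang <- 2 * pi * m / period
  mu <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  mu %% period
}
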