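# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

KMH_TO_MS <- 1 / 3.6

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# Horizontal (x, y) ranges from points (n x 2 matrix) to each sensor.
horizontal_ranges <- function(xy, array) {
  s <- array$sensors
  nx <- nrow(xy)
  R <- matrix(0, nx, nrow(s))
  for (k in seq_len(nrow(s))) {
    R[, k] <- sqrt((xy[, 1] - s$x[k])^2 + (xy[, 2] - s$y[k])^2)
  }
  R
}

file_header_line <- function(seed, config_hash = NA_character_) {
  sprintf("# songtrack seed=%s config_md5=%s",
          ifelse(is.null(seed), "NA", as.character(seed)),
          ifelse(is.na(config_hash), "NA", config_hash))
}

write_table_with_header <- function(df, file, header, sep = ",") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

read_table_with_header <- function(file, sep = ",") {
  utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
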