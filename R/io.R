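# plain-text file dialect: CSV body with a '#'-prefixed metadata header ----
#
#   # monofilm isotherm v1
#   # temperature_C: 20
#   # component: POPC 0.5
#   # component: Chol 0.5
#   # provenance: barrier_speed=20 cm2/min
#   area_A2,pressure_mN_m
#   102.5,0.0132
#   ...

fmt_num <- function(x) sprintf("%.17g", x)

#' Write an isotherm to the monofilm CSV dialect
#'
#' Numeric values are written with 17 significant digits so that
#' `write_isotherm(read_isotherm(f), f2)` reproduces `f` byte for byte for
#' files produced by this writer.
#'
#' @param iso an [isotherm].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  hdr <- c("# monofilm isotherm v1",
           sprintf("# temperature_C: %s", fmt_num(iso$temperature)),
           sprintf("# component: %s %s", iso$components$component_id,
                   fmt_num(iso$components$mole_fraction)))
  if (length(iso$provenance)) {
    hdr <- c(hdr, sprintf("# provenance: %s=%s", names(iso$provenance),
                          vapply(iso$provenance, function(v)
                            paste(format(v), collapse = " "), "")))
  }
  body <- c("area_A2,pressure_mN_m",
            paste(fmt_num(iso$area), fmt_num(iso$pressure), sep = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an isotherm from the monofilm CSV dialect
#'
#' Parses the `#`-prefixed metadata header (temperature, composition,
#' provenance) and the two-column numeric body, then validates and
#' normalizes via [isotherm()] (compression order, duplicate averaging).
#'
#' @param path file path.
#' @return an [isotherm].
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) {
    mf_error(sprintf("file not found: %s", path), "mf_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta <- sub("^#\\s*", "", lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) {
    mf_error(sprintf("%s: no data rows found", path), "mf_parse_error")
  }
  header <- tolower(gsub("\\s", "", body[1L]))
  cols <- strsplit(header, ",")[[1L]]
  ia <- match("area_a2", cols)
  ip <- match("pressure_mn_m", cols)
  if (is.na(ia) || is.na(ip)) {
    mf_error(sprintf(
      "%s: header must label columns area_A2 and pressure_mN_m", path),
      "mf_parse_error")
  }
  rows <- strsplit(body[-1L], ",")
  bad_len <- which(lengths(rows) < max(ia, ip))
  if (length(bad_len)) {
    mf_error(sprintf("%s: malformed data row %d", path, bad_len[1L]),
             "mf_parse_error")
  }
  num <- function(v, what) {
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) {
      i <- which(is.na(x))[1L]
      mf_error(sprintf("%s: non-numeric %s value '%s' in data row %d",
                       path, what, v[i], i), "mf_parse_error")
    }
    x
  }
  area <- num(vapply(rows, `[[`, "", ia), "area")
  pressure <- num(vapply(rows, `[[`, "", ip), "pressure")

  temperature <- NA_real_
  comp_id <- character()
  comp_x <- numeric()
  provenance <- list()
  for (m in meta) {
    if (grepl("^temperature_C:", m)) {
      temperature <- suppressWarnings(
        as.numeric(trimws(sub("^temperature_C:", "", m))))
    } else if (grepl("^component:", m)) {
      parts <- strsplit(trimws(sub("^component:", "", m)), "\\s+")[[1L]]
      if (length(parts) != 2L) {
        mf_error(sprintf("%s: malformed component line '%s'", path, m),
                 "mf_parse_error")
      }
      comp_id <- c(comp_id, parts[1L])
      comp_x <- c(comp_x, suppressWarnings(as.numeric(parts[2L])))
    } else if (grepl("^provenance:", m)) {
      kv <- sub("^provenance:\\s*", "", m)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq > 0) {
        provenance[[substr(kv, 1L, eq - 1L)]] <-
          substr(kv, eq + 1L, nchar(kv))
      }
    }
  }
  if (!is.finite(temperature)) {
    mf_error(sprintf("%s: metadata must supply '# temperature_C: <value>'",
                     path), "mf_parse_error")
  }
  if (!length(comp_id) || anyNA(comp_x)) {
    mf_error(sprintf("%s: metadata must supply '# component: <id> <frac>'",
                     path), "mf_parse_error")
  }
  comps <- data.frame(component_id = comp_id, mole_fraction = comp_x,
                      stringsAsFactors = FALSE)
  isotherm(area, pressure, temperature, comps, provenance)
}

#' Export an isotherm (with metadata) as JSON
#'
#' @param iso an [isotherm].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
isotherm_to_json <- function(iso, path = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  obj <- list(
    units = list(area = "A^2/molecule", pressure = "mN/m",
                 temperature = "C"),
    temperature = iso$temperature,
    components = iso$components,
    provenance = iso$provenance,
    points = data.frame(area = iso$area, pressure = iso$pressure))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
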