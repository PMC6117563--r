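#' Read an idealized record in DWT format
#'
#' Parses the tab-separated DWT dialect: one or more segments, each headed by
#' a line starting with `Segment:` (other header fields are ignored),
#' followed by lines of integer class and dwell duration in milliseconds.
#' Class 0 maps to shut; any class >= 1 maps to open. Consecutive dwells of
#' the same class are merged with a warning.
#'
#' @param path file path.
#' @return A [dwell_sequence()] (durations in seconds).
#' @export
read_dwt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  seg_starts <- grep("^Segment:", lines)
  if (!length(seg_starts)) stop("malformed DWT: no 'Segment:' header")
  seg_ends <- c(seg_starts[-1] - 1L, length(lines))
  segs <- list()
  for (i in seq_along(seg_starts)) {
    body <- lines[seq.int(seg_starts[i] + 1L, seg_ends[i])]
    body <- body[!grepl("^[A-Za-z]", body)]
    if (!length(body)) next
    parts <- do.call(rbind, strsplit(body, "[\t ]+"))
    cl <- as.integer(parts[, 1]); ms <- as.numeric(parts[, 2])
    if (anyNA(cl) || anyNA(ms)) stop("malformed DWT dwell line in segment ", i)
    classes <- ifelse(cl >= 1L, "open", "shut")
    ## auto-merge non-alternating runs
    if (any(classes[-1] == classes[-length(classes)])) {
      warning("non-alternating classes in DWT segment ", i, ": merging")
      r <- rle(classes)
      grp <- rep(seq_along(r$lengths), r$lengths)
      ms <- as.numeric(rowsum(ms, grp))
      classes <- r$values
    }
    segs[[length(segs) + 1L]] <- data.frame(segment = i, class = classes,
                                            duration = ms * 1e-3,
                                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, segs)
  dwell_sequence(df$duration, df$class, df$segment)
}

#' Write an idealized record in DWT format
#'
#' @param dwells a [dwell_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dwt <- function(dwells, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (segi in unique(dwells$segment)) {
    s <- dwells[dwells$segment == segi, ]
    writeLines(sprintf("Segment: %d  Dwells: %d", segi, nrow(s)), con)
    writeLines(sprintf("%d\t%.10g", as.integer(s$class == "open"),
                       s$duration * 1e3), con)
  }
  invisible(path)
}

#' Read/write the canonical dwell CSV
#'
#' Plain CSV with header `segment,class,duration_s` (class 0 = shut,
#' 1 = open), durations in seconds with full decimal round trip.
#'
#' @param path file path.
#' @return `read_dwell_csv()`: a [dwell_sequence()] (empty file gives an
#'   empty data.frame with a warning); `write_dwell_csv()`: `path`,
#'   invisibly.
#' @export
read_dwell_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty dwell file")
    return(dwell_sequence(numeric(0)[0], character(0)))
  }
  need <- c("segment", "class", "duration_s")
  if (!all(need %in% names(df)))
    stop("dwell CSV must have columns: ", paste(need, collapse = ", "))
  dwell_sequence(df$duration_s, df$class, df$segment)
}

#' @rdname read_dwell_csv
#' @param dwells a [dwell_sequence()].
#' @export
write_dwell_csv <- function(dwells, path) {
  df <- data.frame(segment = dwells$segment,
                   class = as.integer(dwells$class == "open"),
                   duration_s = sprintf("%.10g", dwells$duration))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a mechanism as JSON
#'
#' The JSON schema holds `states` (id, class, labels), `rates` (name, value,
#' ligand, fixed), `transitions` (from, to, rate, factor) and `constraints`
#' (`fixed`, `equal` pairs, `mr` as `"auto"` or explicit cycles). A document
#' may instead name a `preset` (`"tetramer"`, `"dimer_desens"`, `"binding"`,
#' `"all_four"`) with a `rates` table and optional `statistical_factors`
#' flag, which is dispatched to the corresponding builder.
#'
#' @param path file path.
#' @return A [mechanism()].
#' @export
read_mechanism_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.null(doc$preset)) {
    rates <- do.call(nmda_rates, as.list(doc$rates))
    sf <- doc$statistical_factors %||% TRUE
    return(switch(doc$preset,
                  tetramer = build_tetramer(rates, sf),
                  dimer_desens = build_dimer_desensitization(rates, sf),
                  binding = build_binding_extended(rates, sf),
                  all_four = build_all_four_gate(
                    rates, doc$extension %||% "dimer", sf),
                  stop("unknown preset: ", doc$preset)))
  }
  rates <- lapply(seq_len(nrow(doc$rates)), function(i) {
    r <- doc$rates[i, ]
    rate_param(r$name, r$value,
               if (!is.null(r$ligand) && !is.na(r$ligand)) r$ligand
               else NA_character_,
               isTRUE(r$fixed))
  })
  constraints <- list(
    fixed = doc$constraints$fixed %||% character(0),
    equal = doc$constraints$equal %||% list())
  mech <- mechanism(doc$states, rates, doc$transitions, constraints)
  mr <- doc$constraints$mr
  if (identical(mr, "auto")) mech <- enforce_mr(mech)
  else if (!is.null(mr) && length(mr$rate)) {
    cyc <- mr$cycle
    if (is.matrix(cyc)) cyc <- lapply(seq_len(nrow(cyc)), function(i) cyc[i, ])
    else if (is.character(cyc)) cyc <- list(cyc)
    mech$constraints$mr <- lapply(seq_along(mr$rate), function(i)
      list(rate = mr$rate[i], cycle = cyc[[i]]))
    mech <- apply_mr(mech)
  }
  mech
}

#' @rdname read_mechanism_json
#' @param mech a [mechanism()].
#' @export
write_mechanism_json <- function(mech, path) {
  doc <- list(
    states = mech$states,
    rates = data.frame(
      name = names(mech$rates),
      value = vapply(mech$rates, function(r) r$value, numeric(1)),
      ligand = vapply(mech$rates, function(r) r$ligand, character(1)),
      fixed = vapply(mech$rates, function(r) r$fixed, logical(1)),
      stringsAsFactors = FALSE),
    transitions = mech$transitions,
    constraints = list(
      fixed = mech$constraints$fixed,
      equal = mech$constraints$equal,
      mr = list(rate = vapply(mech$constraints$mr, `[[`, "", "rate"),
                cycle = lapply(mech$constraints$mr, `[[`, "cycle"))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a waveform as CSV
#'
#' @param w a [respond()] waveform.
#' @param path output path.
#' @export
write_waveform_csv <- function(w, path) {
  df <- data.frame(t = sprintf("%.10g", w$time),
                   popen = sprintf("%.10g", w$popen))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
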