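## TPS landmark files, flower/organ metadata tables, pairing-scheme files,
## and whole-dataset round trips. Units are millimeters end-to-end; TPS
## SCALE= factors are applied on read.

#' Read landmark configurations
#'
#' Reads a TPS landmark file (`LM=`, coordinate lines, optional `ID=`,
#' `SCALE=`, `IMAGE=`) or a delimited long-format table (columns
#' `organ_id, x, y`, landmarks in file order). Landmark counts are validated
#' against the organ type; any scale factor is applied so coordinates come
#' back in mm.
#'
#' @param path File path (`.tps`/`.TPS`, else treated as delimited).
#' @param organ_type Organ type of every configuration in the file.
#' @return List of [landmark_config()]s (flower IDs and orientations unset;
#'   see [join_metadata()]).
#' @export
read_landmarks <- function(path, organ_type) {
  organ_type <- match.arg(organ_type, organ_types())
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.tps$", path, ignore.case = TRUE))
    read_tps(path, organ_type)
  else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("organ_id", "x", "y") %in% names(df)))
      stop("delimited landmark file needs columns organ_id, x, y",
           call. = FALSE)
    lapply(split(df, factor(df$organ_id, unique(df$organ_id))), function(d)
      landmark_config(cbind(d$x, d$y), organ_type, organ_id = d$organ_id[1L]))
  }
}

read_tps <- function(path, organ_type) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines)
  if (!length(starts)) stop("not a TPS file (no LM= records): ", path,
                            call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM=", "", block[1L]))
    if (is.na(k) || length(block) < k + 1L)
      stop(sprintf("malformed TPS record %d in %s", r, path), call. = FALSE)
    coords <- block[2:(k + 1L)]
    if (any(grepl("=", coords, fixed = TRUE)))
      stop(sprintf("malformed TPS record %d in %s: fewer coordinate lines than LM=%d",
                   r, path, k), call. = FALSE)
    m <- do.call(rbind, lapply(strsplit(coords, "[ \t,]+"), function(v) {
      v <- suppressWarnings(as.numeric(v))
      if (length(v) != 2L || anyNA(v))
        stop(sprintf("malformed coordinate line in TPS record %d of %s", r, path),
             call. = FALSE)
      v
    }))
    rest <- if (length(block) > k + 1L) block[(k + 2L):length(block)] else character()
    id <- sub("^ID=", "", grep("^ID=", rest, value = TRUE)[1L])
    if (is.na(id)) id <- sprintf("record_%d", r)
    scale <- suppressWarnings(as.numeric(
      sub("^SCALE=", "", grep("^SCALE=", rest, value = TRUE)[1L])))
    if (!is.na(scale)) m <- m * scale
    if (k != ORGAN_LANDMARKS[[organ_type]])
      stop(sprintf("TPS record '%s' (record %d in %s): expected %d landmarks for %s, found %d",
                   id, r, path, ORGAN_LANDMARKS[[organ_type]], organ_type, k),
           call. = FALSE)
    out[[r]] <- landmark_config(m, organ_type, organ_id = id)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Coordinates are written in mm at full double precision with `SCALE=1`;
#' [read_landmarks()] of the result reproduces the input exactly.
#'
#' @param configs List of [landmark_config()]s (one organ type).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in configs) {
    m <- cfg$coords
    writeLines(c(sprintf("LM=%d", nrow(m)),
                 sprintf("%.17g %.17g", m[, 1L], m[, 2L]),
                 sprintf("ID=%s", cfg$organ_id),
                 "SCALE=1.0"), con)
  }
  invisible(path)
}

#' Attach flower metadata to organ configurations
#'
#' Binds each organ to its flower record, deriving the spathe orientation,
#' the relative orientation, and the flower's alignment class. Organs whose
#' `flower_id` is absent from `records` are an error (all offenders listed);
#' flowers with missing organs are retained and reported via a message, and
#' analyses simply use the available organs per type.
#'
#' @param configs List of [landmark_config()]s with `flower_id` and
#'   `compass_orientation` set.
#' @param records Flower-record data frame with columns `flower_id`,
#'   `spathe_orientation`, and optionally `plant_id`.
#' @return Data frame with one row per organ: `organ_id`, `flower_id`,
#'   `plant_id`, `organ_type`, `compass_orientation`, `spathe_orientation`,
#'   `relative_orientation`, `alignment`.
#' @export
join_metadata <- function(configs, records) {
  organs <- data.frame(
    organ_id = vapply(configs, `[[`, "", "organ_id"),
    flower_id = vapply(configs, `[[`, "", "flower_id"),
    organ_type = vapply(configs, `[[`, "", "organ_type"),
    compass_orientation = vapply(configs, function(x)
      as.integer(x$compass_orientation), 1L),
    stringsAsFactors = FALSE)
  unknown <- setdiff(organs$flower_id, records$flower_id)
  if (length(unknown))
    stop("organs reference flower_id(s) missing from records: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  i <- match(organs$flower_id, records$flower_id)
  organs$plant_id <- if ("plant_id" %in% names(records))
    records$plant_id[i] else NA_character_
  organs$spathe_orientation <- records$spathe_orientation[i]
  organs$relative_orientation <- relative_orientation(
    organs$compass_orientation, organs$spathe_orientation)
  ali <- vapply(
    split(organs$relative_orientation[organs$organ_type == "fall"],
          organs$flower_id[organs$organ_type == "fall"]),
    classify_alignment, "")
  organs$alignment <- unname(ali[organs$flower_id])
  incomplete <- names(which(table(organs$flower_id) < 9L))
  incomplete <- intersect(incomplete, records$flower_id)
  if (length(incomplete))
    message(length(incomplete),
            " flower(s) with missing organs retained (available-case analysis): ",
            paste(head(incomplete, 5L), collapse = ", "),
            if (length(incomplete) > 5L) ", ...")
  organs
}

#' Read or write a pairing-scheme file
#'
#' Plain-text format: a line `organ_type <type>`, one `pair <left> <right>`
#' line per landmark pair, and a single `midline <i> <j> ...` line. Blank
#' lines and `#` comments are ignored.
#'
#' @param path File path.
#' @param pairing A [pairing_scheme()].
#' @return `read_pairing()` returns a [pairing_scheme()].
#' @export
read_pairing <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  key <- vapply(toks, `[[`, "", 1L)
  ot <- toks[[match("organ_type", key)]][2L]
  pairs <- do.call(rbind, lapply(toks[key == "pair"], function(v)
    as.integer(v[2:3])))
  midline <- as.integer(toks[[match("midline", key)]][-1L])
  pairing_scheme(ot, pairs, midline)
}

#' @rdname read_pairing
#' @export
write_pairing <- function(pairing, path) {
  writeLines(c(paste("organ_type", pairing$organ_type),
               sprintf("pair %d %d", pairing$pairs[, 1L], pairing$pairs[, 2L]),
               paste("midline", paste(pairing$midline, collapse = " "))),
             path)
  invisible(path)
}

#' Write or read a whole flower dataset as plain-text files
#'
#' `write_dataset()` writes one TPS file per organ type (`fall.tps`,
#' `standard.tps`, `style_branch.tps`), the organ metadata (`organs.csv`),
#' the flower records (`flowers.csv`) and one pairing file per organ type.
#' `read_dataset()` reverses the operation.
#'
#' @param dataset A `flower_dataset` from [generate_dataset()] (or a list
#'   with `records` and `configs`).
#' @param dir Directory (created if needed).
#' @param pairings Named list of pairing schemes; defaults to the built-in
#'   schemes on read if no pairing files are present.
#' @return `read_dataset()` returns a list with `records`, `configs`,
#'   `organs` (the [join_metadata()] table) and `pairings`.
#' @export
write_dataset <- function(dataset, dir,
                          pairings = lapply(setNames(nm = organ_types()),
                                            default_pairing)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ot in organ_types()) {
    cfgs <- organ_configs(dataset, ot)
    if (length(cfgs)) write_tps(cfgs, file.path(dir, paste0(ot, ".tps")))
    write_pairing(pairings[[ot]], file.path(dir, paste0("pairing_", ot, ".txt")))
  }
  organs <- data.frame(
    organ_id = vapply(dataset$configs, `[[`, "", "organ_id"),
    flower_id = vapply(dataset$configs, `[[`, "", "flower_id"),
    organ_type = vapply(dataset$configs, `[[`, "", "organ_type"),
    compass_orientation = vapply(dataset$configs, function(x)
      as.integer(x$compass_orientation), 1L))
  write.csv(organs, file.path(dir, "organs.csv"), row.names = FALSE)
  write.csv(dataset$records, file.path(dir, "flowers.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  records <- read.csv(file.path(dir, "flowers.csv"), stringsAsFactors = FALSE)
  organs_meta <- read.csv(file.path(dir, "organs.csv"), stringsAsFactors = FALSE)
  configs <- list()
  pairings <- list()
  for (ot in organ_types()) {
    tps <- file.path(dir, paste0(ot, ".tps"))
    if (file.exists(tps)) {
      cfgs <- read_landmarks(tps, ot)
      i <- match(vapply(cfgs, `[[`, "", "organ_id"), organs_meta$organ_id)
      if (anyNA(i))
        stop("TPS organ IDs missing from organs.csv in ", dir, call. = FALSE)
      cfgs <- lapply(seq_along(cfgs), function(j) {
        cfgs[[j]]$flower_id <- organs_meta$flower_id[i[j]]
        cfgs[[j]]$compass_orientation <- organs_meta$compass_orientation[i[j]]
        cfgs[[j]]
      })
      configs <- c(configs, cfgs)
    }
    pf <- file.path(dir, paste0("pairing_", ot, ".txt"))
    pairings[[ot]] <- if (file.exists(pf)) read_pairing(pf)
                      else default_pairing(ot)
  }
  list(records = records, configs = configs,
       organs = join_metadata(configs, records), pairings = pairings)
}
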