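#' @keywords internal
"_PACKAGE"

WELL_ROLES <- c("DRUG", "DMSO_CONTROL", "NAI_POSITIVE", "PBS_NEGATIVE")
PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

SCREEN_COLUMNS <- c("plate_id", "well", "role", "drug_id", "dose_uM",
                    "yfp0", "yfp_c1", "yfp_c2", "yfp_c3", "yfp_c4",
                    "viability")

#' Screen analysis configuration
#'
#' Bundles the tunable parameters of the primary-screen scoring pipeline.
#'
#' @param hit_threshold DeltaYFP cutoff above which a drug well is a hit
#'   (strict inequality by default). The primary screen calls hits at
#'   DeltaYFP > 1.5.
#' @param viability_floor minimum relative viability (fraction of vehicle)
#'   for a drug to be counted; drugs below it are treated as cytotoxic and
#'   never called hits.
#' @param trim_proportion total proportion of values excluded by the
#'   interquartile (trimmed) mean, spreadsheet TRIMMEAN semantics. 0.5
#'   retains the central half.
#' @param cycles_used which post-injection kinetic cycle supplies the
#'   "after" fluorescence reading (1-4).
#' @param strict_hit_inequality if TRUE a well at exactly the threshold is
#'   not a hit.
#' @param zprime_floor per-plate Z-prime below which QC flags the plate.
#' @param rng_seed integer seed recorded in run manifests.
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(hit_threshold = 1.5,
                          viability_floor = 0.70,
                          trim_proportion = 0.5,
                          cycles_used = 4L,
                          strict_hit_inequality = TRUE,
                          zprime_floor = 0.5,
                          rng_seed = 1L) {
  stopifnot(hit_threshold > 0,
            trim_proportion > 0, trim_proportion < 1,
            viability_floor >= 0,
            cycles_used %in% 1:4)
  structure(list(hit_threshold = hit_threshold,
                 viability_floor = viability_floor,
                 trim_proportion = trim_proportion,
                 cycles_used = as.integer(cycles_used),
                 strict_hit_inequality = isTRUE(strict_hit_inequality),
                 zprime_floor = zprime_floor,
                 rng_seed = as.integer(rng_seed)),
            class = "screen_config")
}

#' Read or write a screen configuration as YAML
#' @param path file path.
#' @return `read_screen_config` returns a `screen_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(screen_config, vals[intersect(names(vals),
                                        names(formals(screen_config)))])
}

#' @rdname read_screen_config
#' @param config a `screen_config`.
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# "B02" / "b2" -> list(row = "B", column = 2); NA row on failure
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  row <- substr(well, 1, 1)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  bad <- !(row %in% PLATE_ROWS) | is.na(col) | !(col %in% PLATE_COLS)
  row[bad] <- NA_character_
  col[bad] <- NA_integer_
  list(row = row, column = col)
}

format_well <- function(row, column) {
  sprintf("%s%02d", row, as.integer(column))
}

#' Read a long-format plate screen CSV
#'
#' One row per well. Required columns: `plate_id`, `well` (e.g. "B02"),
#' `role` (DRUG, DMSO_CONTROL, NAI_POSITIVE, PBS_NEGATIVE), `drug_id`,
#' `dose_uM`, `yfp0`, `yfp_c1`..`yfp_c4`, `viability`. Wells with
#' non-positive pre-injection fluorescence or no usable post-injection
#' reading are kept but flagged non-analyzable and excluded from all
#' normalization statistics (never imputed); exclusions are attached as the
#' `"exclusions"` attribute with line numbers.
#'
#' @param path CSV file path.
#' @param quiet suppress the INFO log line.
#' @return a data frame of kinetic wells with parsed `row`, `column` and an
#'   `analyzable` flag.
#' @export
read_screen <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("screen file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SCREEN_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("screen CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$drug_id[!is.na(raw$drug_id) & raw$drug_id == ""] <- NA_character_
  as_kinetic_wells(raw[SCREEN_COLUMNS], source = path, quiet = quiet)
}

# Validate and annotate a raw well table (shared by read_screen and the
# simulator, which builds the same shape in memory).
as_kinetic_wells <- function(raw, source = "<memory>", quiet = FALSE) {
  n <- nrow(raw)
  pw <- parse_well(raw$well)
  bad_addr <- which(is.na(pw$row))
  if (length(bad_addr)) {
    stop("invalid well address at data line(s) ",
         paste(utils::head(bad_addr, 5), collapse = ", "),
         " of ", source, " (e.g. '", raw$well[bad_addr[1]], "')")
  }
  raw$row <- pw$row
  raw$column <- pw$column
  raw$well <- format_well(raw$row, raw$column)

  key <- paste(raw$plate_id, raw$well)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1]
    stop("duplicate well ", raw$plate_id[first], "/", raw$well[first],
         " in ", source)
  }

  bad_role <- !(raw$role %in% WELL_ROLES)
  if (any(bad_role)) {
    stop("unknown role '", raw$role[which(bad_role)[1]], "' at data line ",
         which(bad_role)[1], " of ", source)
  }

  cyc <- as.matrix(raw[paste0("yfp_c", 1:4)])
  analyzable <- is.finite(raw$yfp0) & raw$yfp0 > 0 &
    rowSums(is.finite(cyc)) >= 1
  raw$analyzable <- analyzable

  excl <- data.frame(line = which(!analyzable) + 1L,
                     plate_id = raw$plate_id[!analyzable],
                     well = raw$well[!analyzable],
                     reason = ifelse(!is.finite(raw$yfp0[!analyzable]) |
                                       raw$yfp0[!analyzable] <= 0,
                                     "yfp0 <= 0 or missing",
                                     "no post-injection reading"),
                     stringsAsFactors = FALSE)
  attr(raw, "exclusions") <- excl
  if (!quiet) {
    message(sprintf("read_screen: %d wells from %d plate(s), %d excluded",
                    n, length(unique(raw$plate_id)), nrow(excl)))
  }
  raw
}

#' Write simulated or externally assembled wells back to the screen CSV dialect
#' @param wells kinetic well data frame (as from [read_screen] or
#'   [simulate_screen]).
#' @param path output CSV path.
#' @export
write_screen <- function(wells, path) {
  out <- wells[SCREEN_COLUMNS]
  ord <- order(out$plate_id, substr(out$well, 1, 1),
               as.integer(substring(out$well, 2)))
  utils::write.csv(out[ord, ], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

RESULT_COLUMNS <- c("plate", "well", "drug_id", "pct_yfp", "s_iqm",
                    "s_iqmw", "delta_yfp", "viability", "hit")
RESULT_DIGITS <- 8

#' Write normalized screen results as TSV
#'
#' Deterministic column order and row sort (plate, row, column); floats at
#' fixed precision (8 significant digits).
#'
#' @param wells normalized well data frame (the `wells` element of
#'   [score_screen] output).
#' @param path output TSV path.
#' @export
write_results <- function(wells, path) {
  need <- c("plate_id", "well", "drug_id", "pct_yfp", "s_iqm", "s_iqmw",
            "delta_yfp", "viability", "hit")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols)) {
    stop("wells are not normalized; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(plate = wells$plate_id,
                    well = wells$well,
                    drug_id = wells$drug_id,
                    stringsAsFactors = FALSE)
  for (col in c("pct_yfp", "s_iqm", "s_iqmw", "delta_yfp", "viability")) {
    out[[col]] <- signif(wells[[col]], RESULT_DIGITS)
  }
  out$hit <- wells$hit
  ord <- order(out$plate, substr(out$well, 1, 1),
               as.integer(substring(out$well, 2)))
  utils::write.table(out[ord, RESULT_COLUMNS], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Validate plate layout against control requirements
#'
#' Report-only check that every plate carries positive (NaI) and negative
#' (PBS) control wells, that the screen has enough DMSO wells for the
#' DeltaYFP denominator, and that occupancy is even across plates.
#'
#' @param wells kinetic well data frame.
#' @return data frame of findings (`plate_id`, `finding`); zero rows when
#'   the layout is clean.
#' @export
validate_layout <- function(wells) {
  findings <- data.frame(plate_id = character(), finding = character(),
                         stringsAsFactors = FALSE)
  add <- function(plate, msg) {
    rbind(findings, data.frame(plate_id = plate, finding = msg,
                               stringsAsFactors = FALSE))
  }
  for (p in unique(wells$plate_id)) {
    roles <- wells$role[wells$plate_id == p]
    if (!any(roles == "NAI_POSITIVE")) {
      findings <- add(p, "no NAI_POSITIVE control wells")
    }
    if (!any(roles == "PBS_NEGATIVE")) {
      findings <- add(p, "no PBS_NEGATIVE control wells")
    }
  }
  n_dmso <- sum(wells$role == "DMSO_CONTROL")
  if (n_dmso == 0) {
    findings <- add("<screen>",
                    "no DMSO_CONTROL wells: DeltaYFP is uncomputable (zero-well DMSO SD)")
  } else if (n_dmso < 2) {
    findings <- add("<screen>",
                    "fewer than 2 DMSO_CONTROL wells: screen-wide DMSO SD undefined")
  }
  # uneven occupancy: positions used on some plates but missing on others
  plates <- unique(wells$plate_id)
  if (length(plates) > 1) {
    pos_all <- unique(wells$well)
    for (p in plates) {
      gap <- setdiff(pos_all, wells$well[wells$plate_id == p])
      if (length(gap)) {
        findings <- add(p, paste0("occupancy gap: missing position(s) ",
                                  paste(utils::head(sort(gap), 6),
                                        collapse = ", ")))
      }
    }
  }
  findings
}
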