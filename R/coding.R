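#' Canonical ordering of the 20 characters
#'
#' Eight stability characters first (pitch at 0/15/75/equilibrium, then
#' roll and yaw at 15/75), followed by the twelve control-effectiveness
#' characters (tail dorsiflexion and symmetric protraction in pitch,
#' asymmetric wing tuck and pronation/supination in roll, tail lateral
#' flexion and pronation/supination in yaw, each at 15 and 75 degrees).
#'
#' @return data frame with `label`, `kind`, `axis`, `movement`,
#'   `evaluation_point` and the NEXUS `symbols` string for each character.
#' @export
character_order <- function() {
  stab <- data.frame(
    label = c("stab_pitch_0", "stab_pitch_15", "stab_pitch_75",
              "stab_pitch_eq", "stab_roll_15", "stab_roll_75",
              "stab_yaw_15", "stab_yaw_75"),
    kind = "stability",
    axis = c("pitch", "pitch", "pitch", "pitch", "roll", "roll",
             "yaw", "yaw"),
    movement = "none",
    evaluation_point = c("0", "15", "75", "eq", "15", "75", "15", "75"),
    symbols = "012"
  )
  mv <- data.frame(
    axis = c("pitch", "pitch", "roll", "roll", "yaw", "yaw"),
    movement = c("tail_dorsiflexion", "sym_protraction", "asym_wing_tuck",
                 "asym_pron_sup", "tail_lateral", "asym_pron_sup"),
    short = c("taildorsi", "symprot", "wingtuck", "pronsup", "taillat",
              "pronsup")
  )
  ctrl <- do.call(rbind, lapply(seq_len(nrow(mv)), function(k) {
    data.frame(
      label = sprintf("ctrl_%s_%s_%s", mv$axis[k], mv$short[k], c(15, 75)),
      kind = "control", axis = mv$axis[k], movement = mv$movement[k],
      evaluation_point = c("15", "75"), symbols = "01")
  }))
  rbind(stab, ctrl)
}

#' Discretize a stability slope via its confidence interval
#'
#' Marginal if the interval straddles zero, stable if it lies wholly below
#' zero, unstable if wholly above; `NA` estimates code as missing `"?"`.
#'
#' @param slope,ci_low,ci_high vectors from a stability
#'   [estimate_derivatives()] row.
#' @return character vector over {"stable", "marginal", "unstable", "?"}.
#' @export
code_stability <- function(slope, ci_low, ci_high) {
  out <- ifelse(is.na(slope) | is.na(ci_low) | is.na(ci_high), "?",
                ifelse(ci_low <= 0 & ci_high >= 0, "marginal",
                       ifelse(slope < 0, "stable", "unstable")))
  out
}

#' Discretize control effectiveness via the weather-vane threshold
#'
#' Effective iff `|slope| > threshold` (strict), with the default threshold
#' 0.09 rad^-1 -- the moment-coefficient derivative needed to overcome
#' measured weather-vane stability, equivalently to displace the center of
#' pressure by about 10% of body length. The absolute value is used because
#' sign encodes the direction of the generated moment, not the capacity to
#' generate one.
#'
#' @param slope control-effectiveness estimates, rad^-1.
#' @param threshold effectiveness threshold, rad^-1.
#' @return character vector over {"effective", "ineffective", "?"}.
#' @export
code_control <- function(slope, threshold = 0.09) {
  stopifnot(threshold >= 0)
  ifelse(is.na(slope), "?",
         ifelse(abs(slope) > threshold, "effective", "ineffective"))
}

state_to_symbol <- function(state, kind) {
  map <- if (kind == "stability") {
    c(stable = "0", marginal = "1", unstable = "2", `?` = "?")
  } else {
    c(ineffective = "0", effective = "1", `?` = "?")
  }
  unname(map[state])
}

symbol_to_state <- function(symbol, kind) {
  map <- if (kind == "stability") {
    c(`0` = "stable", `1` = "marginal", `2` = "unstable", `?` = "?")
  } else {
    c(`0` = "ineffective", `1` = "effective", `?` = "?")
  }
  unname(map[symbol])
}

#' Assemble the taxa x 20 character matrix
#'
#' Codes every derivative estimate with [code_stability()] /
#' [code_control()] and arranges them in the [character_order()]. A
#' continuous matrix of the raw slopes is kept alongside the discrete one
#' (exported, but not used by parsimony mapping).
#'
#' @param estimates table from [estimate_derivatives()], any number of taxa.
#' @param threshold control-effectiveness threshold, rad^-1.
#' @return object of class `character_matrix`: list with `taxa`,
#'   `characters` (the [character_order()] table), `states` (character
#'   matrix, words), `slopes` (numeric matrix).
#' @export
build_character_matrix <- function(estimates, threshold = 0.09) {
  ord <- character_order()
  taxa <- unique(estimates$taxon)
  states <- matrix("?", length(taxa), nrow(ord),
                   dimnames = list(taxa, ord$label))
  slopes <- matrix(NA_real_, length(taxa), nrow(ord),
                   dimnames = list(taxa, ord$label))
  filled <- matrix(FALSE, length(taxa), nrow(ord),
                   dimnames = list(taxa, ord$label))
  for (i in seq_len(nrow(estimates))) {
    e <- estimates[i, ]
    hit <- which(ord$kind == e$kind & ord$axis == e$axis &
                   ord$movement == e$movement &
                   ord$evaluation_point == e$evaluation_point)
    if (!length(hit)) next
    lab <- ord$label[hit]
    if (filled[e$taxon, lab]) {
      stop("build_character_matrix: duplicate estimate for (",
           e$taxon, ", ", lab, ")")
    }
    filled[e$taxon, lab] <- TRUE
    slopes[e$taxon, lab] <- e$slope
    states[e$taxon, lab] <- if (e$kind == "stability") {
      code_stability(e$slope, e$ci_low, e$ci_high)
    } else {
      code_control(e$slope, threshold)
    }
  }
  structure(list(taxa = taxa, characters = ord, states = states,
                 slopes = slopes),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix> ", length(x$taxa), " taxa x ",
      nrow(x$characters), " characters\n", sep = "")
  if (length(x$taxa)) {
    sym <- symbol_matrix(x)
    print(apply(sym, 1, paste, collapse = ""))
  }
  invisible(x)
}

symbol_matrix <- function(cm) {
  sym <- cm$states
  for (j in seq_len(ncol(sym))) {
    sym[, j] <- state_to_symbol(cm$states[, j], cm$characters$kind[j])
  }
  sym
}

#' Write a character matrix as a Mesquite-compatible NEXUS DATA block
#'
#' STANDARD datatype, `SYMBOLS="0 1 2"`, `MISSING=?`, with
#' CHARSTATELABELS naming every character. Stability characters use
#' 0=stable, 1=marginal, 2=unstable; control characters 0=ineffective,
#' 1=effective.
#'
#' @param cm a [build_character_matrix()] result.
#' @param path output file.
#' @export
write_nexus_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "character_matrix"))
  sym <- symbol_matrix(cm)
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(cm$taxa),
            nrow(cm$characters)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0 1 2\" MISSING=? GAP=-;",
    "  CHARSTATELABELS",
    paste0("    ", seq_len(nrow(cm$characters)), " ", cm$characters$label,
           c(rep(",", nrow(cm$characters) - 1), ";")),
    "  MATRIX"
  )
  if (length(cm$taxa)) {
    lines <- c(lines, sprintf("    %-24s %s", cm$taxa,
                              apply(sym, 1, paste, collapse = "")))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Export discrete and continuous character matrices as CSV
#'
#' @param cm a [build_character_matrix()] result.
#' @param discrete_path,continuous_path output CSV paths (NULL to skip).
#' @export
write_matrix_csv <- function(cm, discrete_path = NULL,
                             continuous_path = NULL) {
  stopifnot(inherits(cm, "character_matrix"))
  if (!is.null(discrete_path)) {
    utils::write.csv(data.frame(taxon = cm$taxa, cm$states,
                                check.names = FALSE),
                     discrete_path, row.names = FALSE)
  }
  if (!is.null(continuous_path)) {
    utils::write.csv(data.frame(taxon = cm$taxa, cm$slopes,
                                check.names = FALSE),
                     continuous_path, row.names = FALSE)
  }
  invisible(cm)
}
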