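# Trial-design enumeration for the five-experiment battery and piece
# placement on the board.

# Published mesh-occluder menu keyed by the occluded-area proportion used in
# the area-estimation experiment (small, large hole diameters in pixels).
mesh_menu <- function() {
  data.frame(
    proportion = c(0.25, 0.36, 0.43, 0.50, 0.58, 0.65, 0.76),
    small_d = c(25, 30, 35, 39, 40, 54, 58),
    large_d = c(35, 45, 50, 56, 60, 60, 63)
  )
}

#' Default configuration for one experiment's trial design
#'
#' Returns the per-experiment menus of numerosities, conditions, occluders,
#' scales and repetition counts that `enumerate_trials()` expands. The
#' defaults reproduce the published designs; individual entries can be
#' overridden for reduced designs (e.g. fewer repetitions).
#'
#' @param experiment_id integer 1 to 5.
#' @return a named list of design parameters.
#' @export
experiment_config <- function(experiment_id) {
  switch(as.character(experiment_id),
    "1" = list(
      standard = 10L,
      comparisons = c(2L, 4L, 6L, 8L, 9L, 10L, 11L, 12L, 14L, 16L, 18L),
      conditions = c("non_occluded", "occluded", "mixed"),
      repetitions = 10L,
      occluder = "mesh_40_60",
      n_obscured_reps = 1L,
      n_swapped_reps = 1L
    ),
    "2" = list(
      numerosities = 6:14,
      conditions = c("non_occluded", "small_occluder", "large_occluder"),
      repetitions = 10L,
      occluders = c(non_occluded = "none",
                    small_occluder = "mesh_40_60",
                    large_occluder = "mesh_30_45"),
      n_obscured_reps = 1L
    ),
    "3" = list(
      proportions = c(0.25, 0.36, 0.43, 0.50, 0.58, 0.65, 0.76),
      scales = c(1, 0.75, 0.5),
      repetitions_occluded = 10L,
      repetitions_non_occluded = 1L
    ),
    "4" = list(
      numerosities = c(5L, 7L, 10L, 12L, 14L),
      conditions = c("irregular", "regular_across", "regular_outside"),
      repetitions = 10L,
      # bar orientation per numerosity: vertical for 5/10/12, horizontal for 7/14
      orientation = c(`5` = "vertical", `7` = "horizontal", `10` = "vertical",
                      `12` = "vertical", `14` = "horizontal")
    ),
    "5" = list(
      numerosities = 6:14,
      proportions = seq(0.30, 0.70, by = 0.02)
    ),
    stop("unknown experiment_id: ", experiment_id, call. = FALSE)
  )
}

#' Enumerate the trial table of one experiment
#'
#' Expands an experiment's design menus into the full per-trial table:
#' 352 trials for the discrimination experiment (330 test + 11 obscured +
#' 11 swapped), 279 for direct estimation (270 + 9 obscured), 231 for area
#' estimation (210 occluded + 21 non-occluded), 150 for the regularity
#' experiment and 189 for the night-sky experiment. Obscured and swapped
#' trials carry `analyzed = FALSE`.
#'
#' @param experiment_id integer 1 to 5.
#' @param config design menus, defaulting to `experiment_config(experiment_id)`.
#' @return a data.frame with columns `experiment`, `trial`, `condition`,
#'   `n_visible_std`, `n_visible_cmp`, `proportion`, `occluder`, `scale`,
#'   `rep` and `analyzed`.
#' @examples
#' nrow(enumerate_trials(1))  # 352
#' @export
enumerate_trials <- function(experiment_id, config = experiment_config(experiment_id)) {
  experiment_id <- as.integer(experiment_id)
  row_df <- function(condition, n_std, n_cmp, proportion, occluder, scale, rep, analyzed) {
    data.frame(condition = condition, n_visible_std = n_std, n_visible_cmp = n_cmp,
               proportion = proportion, occluder = occluder, scale = scale,
               rep = rep, analyzed = analyzed, stringsAsFactors = FALSE)
  }
  tab <- switch(as.character(experiment_id),
    "1" = {
      g <- expand.grid(rep = seq_len(config$repetitions),
                       condition = config$conditions,
                       cmp = config$comparisons, stringsAsFactors = FALSE)
      test <- row_df(g$condition, config$standard, g$cmp, NA_real_,
                     ifelse(g$condition == "non_occluded", "none", config$occluder),
                     1, g$rep, TRUE)
      obs <- row_df("obscured", config$standard, config$comparisons, NA_real_,
                    config$occluder, 1, seq_len(config$n_obscured_reps), FALSE)
      swp <- row_df("swapped", config$standard, config$comparisons, NA_real_,
                    config$occluder, 1, seq_len(config$n_swapped_reps), FALSE)
      rbind(test, obs, swp)
    },
    "2" = {
      g <- expand.grid(rep = seq_len(config$repetitions),
                       condition = config$conditions,
                       n = config$numerosities, stringsAsFactors = FALSE)
      test <- row_df(g$condition, g$n, NA_integer_, NA_real_,
                     unname(config$occluders[g$condition]), 1, g$rep, TRUE)
      obs <- row_df("obscured", config$numerosities, NA_integer_, NA_real_,
                    config$occluders[["small_occluder"]], 1,
                    seq_len(config$n_obscured_reps), FALSE)
      rbind(test, obs)
    },
    "3" = {
      menu <- mesh_menu()
      occ_label <- function(p) {
        i <- match(p, menu$proportion)
        sprintf("mesh_%d_%d", menu$small_d[i], menu$large_d[i])
      }
      g_occ <- expand.grid(rep = seq_len(config$repetitions_occluded),
                           scale = config$scales, p = config$proportions)
      g_non <- expand.grid(rep = seq_len(config$repetitions_non_occluded),
                           scale = config$scales, p = config$proportions)
      rbind(
        row_df("occluded", NA_integer_, NA_integer_, g_occ$p,
               occ_label(g_occ$p), g_occ$scale, g_occ$rep, TRUE),
        row_df("non_occluded", NA_integer_, NA_integer_, g_non$p,
               "none", g_non$scale, g_non$rep, TRUE)
      )
    },
    "4" = {
      g <- expand.grid(rep = seq_len(config$repetitions),
                       condition = config$conditions,
                       n = config$numerosities, stringsAsFactors = FALSE)
      occ <- paste0(unname(config$orientation[as.character(g$n)]), "_bars")
      row_df(g$condition, g$n, NA_integer_, NA_real_, occ, 1, g$rep, TRUE)
    },
    "5" = {
      g <- expand.grid(p = config$proportions, n = config$numerosities)
      row_df("sky", g$n, NA_integer_, g$p, "clouds", 1, 1L, TRUE)
    },
    stop("unknown experiment_id: ", experiment_id, call. = FALSE)
  )
  data.frame(experiment = experiment_id, trial = seq_len(nrow(tab)), tab,
             stringsAsFactors = FALSE)
}

# Lines of the board that cross (or avoid) a bar occluder. For vertical bars
# the crossing lines are the rows (each row passes under both bars) and the
# clear lines are the uncovered columns; for horizontal bars the roles swap.
bar_lines <- function(board, occluder) {
  covered <- sort(unlist(occluder$bar_extent))
  if (occluder$kind == "vertical_bars") {
    list(across_axis = "row", across = seq_len(board$rows),
         visible_on_line = setdiff(seq_len(board$cols), covered),
         covered_on_line = covered,
         outside_axis = "col", outside = setdiff(seq_len(board$cols), covered),
         outside_len = board$rows)
  } else if (occluder$kind == "horizontal_bars") {
    list(across_axis = "col", across = seq_len(board$cols),
         visible_on_line = setdiff(seq_len(board$rows), covered),
         covered_on_line = covered,
         outside_axis = "row", outside = setdiff(seq_len(board$rows), covered),
         outside_len = board$cols)
  } else {
    stop("regular arrangements require a bar occluder", call. = FALSE)
  }
}

# Choose k positions among `visible` cells of one line so that the number of
# covered cells strictly inside the spanned interval equals `target_covered`
# (exactly if possible, else as close as possible). Used to equate the
# expected hidden count along a partially filled crossing line.
pick_span <- function(visible, covered, k, target_covered) {
  if (k == 0L) return(integer(0))
  combos <- utils::combn(visible, k, simplify = FALSE)
  score <- vapply(combos, function(cells) {
    span <- range(cells)
    abs(sum(covered > span[1] & covered < span[2]) - target_covered)
  }, numeric(1))
  combos[[which.min(score)]]
}

#' Place game pieces on the board
#'
#' Places `n_visible` pieces on cells where they are at least partly visible,
#' with balanced black/white colours. Three arrangements are supported:
#' `irregular` (random cells with no three pieces sharing a board row or
#' column), `regular_across` (pieces fill the visible cells of one or more
#' adjacent board lines that cross the bar occluder) and `regular_outside`
#' (pieces fill uncovered lines that never touch the occluder). For regular
#' arrangements the lines are chosen so that the number of covered cells
#' along the pieces' path matches the density-extrapolation expectation for
#' the same numerosity, making the expected hidden count equal across the
#' three conditions.
#'
#' @param board a `board_spec`.
#' @param occluder an `occluder_spec` or NULL; regular arrangements require
#'   a bar occluder.
#' @param n_visible number of pieces to place.
#' @param arrangement `"irregular"`, `"regular_across"` or `"regular_outside"`.
#' @param rng_seed integer seed; identical seeds give identical layouts.
#' @param geom optional precomputed `occlusion_geometry` (avoids re-rasterizing).
#' @return a data.frame of class `piece_layout` with columns `row`, `col`,
#'   `color`, and attributes `arrangement`, `n_visible`, `seed`.
#' @export
place_pieces <- function(board, occluder = NULL, n_visible,
                         arrangement = c("irregular", "regular_across", "regular_outside"),
                         rng_seed = NULL, geom = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot_scalar_count(n_visible, "n_visible")
  if (is.null(geom)) geom <- occlusion_geometry(board, occluder)
  visible_cells <- which(!geom$hidden, arr.ind = TRUE)
  if (n_visible > nrow(visible_cells)) {
    stop("placement error: n_visible exceeds the number of visible cells", call. = FALSE)
  }
  cells <- with_seed(rng_seed, {
    if (arrangement == "irregular") {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        idx <- sample(nrow(visible_cells), n_visible)
        sel <- visible_cells[idx, , drop = FALSE]
        if (max(c(0L, tabulate(sel[, 1]))) <= 2L && max(c(0L, tabulate(sel[, 2]))) <= 2L) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("placement error: could not avoid three collinear pieces on a board line",
                    call. = FALSE)
      sel
    } else {
      li <- bar_lines(board, occluder)
      ratio <- geom$S_h / geom$S_v
      if (arrangement == "regular_across") {
        per_line <- length(li$visible_on_line)
        n_lines <- ceiling(n_visible / per_line)
        if (n_lines > length(li$across)) {
          stop("placement error: not enough crossing lines for this numerosity", call. = FALSE)
        }
        start <- sample(length(li$across) - n_lines + 1L, 1L)
        lines <- li$across[start:(start + n_lines - 1L)]
        out <- NULL
        remaining <- n_visible
        for (ln in lines) {
          k <- min(per_line, remaining)
          pos <- if (k == per_line) {
            li$visible_on_line
          } else {
            # partial line: match the covered-cell count expected for k pieces
            target <- round_half_up(n_visible * ratio) -
              (n_visible %/% per_line) * length(li$covered_on_line)
            pick_span(li$visible_on_line, li$covered_on_line, k, target)
          }
          out <- rbind(out, if (li$across_axis == "row") cbind(row = ln, col = pos)
                             else cbind(row = pos, col = ln))
          remaining <- remaining - k
        }
        out
      } else { # regular_outside
        per_line <- li$outside_len
        n_lines <- ceiling(n_visible / per_line)
        if (n_lines > length(li$outside)) {
          stop("placement error: not enough clear lines for this numerosity", call. = FALSE)
        }
        lines <- sample(li$outside, n_lines)
        out <- NULL
        remaining <- n_visible
        for (ln in lines) {
          k <- min(per_line, remaining)
          pos <- sort(sample(per_line, k))
          out <- rbind(out, if (li$outside_axis == "col") cbind(row = pos, col = ln)
                             else cbind(row = ln, col = pos))
          remaining <- remaining - k
        }
        out
      }
    }
  })
  colors <- with_seed(if (is.null(rng_seed)) NULL else rng_seed + 1L,
                      sample(rep_len(c("black", "white"), n_visible)))
  layout <- data.frame(row = as.integer(cells[, "row"]), col = as.integer(cells[, "col"]),
                       color = if (n_visible > 0) colors else character(0),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(layout[, c("row", "col")])) {
    stop("placement error: duplicate cell assignment", call. = FALSE)
  }
  structure(layout, class = c("piece_layout", "data.frame"),
            arrangement = arrangement, n_visible = n_visible, seed = rng_seed)
}
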