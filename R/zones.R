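#' Canonical Tree-Maze zone geometry
#'
#' Returns the 39-zone segmentation of the Tree-Maze used throughout the
#' package. The maze is a 1.2 m wide by 1.4 m tall tree: a Home well at the
#' bottom, a vertical stem up to the Decision well, and symmetric left and
#' right branches that each split once more into two goal arms. Wells are
#' H (home), D (decision) and the four goal wells G1/G2 (right branch) and
#' G3/G4 (left branch).
#'
#' Coordinates are continuous cm with the origin at the maze's lower-left
#' corner. Each zone carries a fine-grained segment label (home, stem,
#' decision, left, right, goal_area) and a coarse three-way label
#' (`segment3`: left / stem / right) used by the segment-wise rate
#' statistics; home, stem and decision zones fold into "stem", and goal
#' areas fold into their branch.
#'
#' @return A list with components:
#'   \describe{
#'     \item{zones}{data.frame with columns `zone_id` (0..38), `segment`,
#'       `segment3`, `well` (NA or H/D/G1..G4), `x`, `y` (cm), `linear_pos`
#'       (1..21 position along the linearized H->D->intersection->G path,
#'       shared between left/right equivalents), `branch` (NA, "L", "R").}
#'     \item{adjacency}{list of integer vectors; `adjacency[[z + 1]]` are the
#'       zone_ids adjacent to zone z.}
#'     \item{bounds}{c(xmin, xmax, ymin, ymax) of the maze bounding box.}
#'   }
#' @export
treemaze_zones <- function() {
  z <- data.frame(
    zone_id = 0:38,
    segment = c(
      "home",                      # 0 H
      rep("stem", 9),              # 1-9 stem
      "decision",                  # 10 D
      rep("left", 5),              # 11-15 left approach
      "left",                      # 16 left intersection
      "left", "left", "left", "goal_area",  # 17-20 arm to G4 (outer left)
      "left", "left", "left", "goal_area",  # 21-24 arm to G3 (inner left)
      rep("right", 5),             # 25-29 right approach
      "right",                     # 30 right intersection
      "right", "right", "right", "goal_area",  # 31-34 arm to G1 (outer right)
      "right", "right", "right", "goal_area"   # 35-38 arm to G2 (inner right)
    ),
    well = NA_character_,
    x = NA_real_, y = NA_real_,
    stringsAsFactors = FALSE
  )
  z$well[z$zone_id == 0] <- "H"
  z$well[z$zone_id == 10] <- "D"
  z$well[z$zone_id == 20] <- "G4"
  z$well[z$zone_id == 24] <- "G3"
  z$well[z$zone_id == 34] <- "G1"
  z$well[z$zone_id == 38] <- "G2"

  # centroids: stem vertical at x = 60, branches fan out and up
  xy <- rbind(
    c(60, 6),                                   # H
    cbind(60, seq(16, 80, by = 8)),             # stem 1-9
    c(60, 88),                                  # D
    cbind(seq(52, 20, by = -8), seq(92, 100, by = 2)),  # 11-15 left approach
    c(14, 104),                                 # 16 left intersection
    rbind(c(10, 110), c(6, 118), c(4, 126), c(4, 134)),    # 17-20 -> G4
    rbind(c(20, 112), c(24, 120), c(26, 128), c(28, 134)), # 21-24 -> G3
    cbind(seq(68, 100, by = 8), seq(92, 100, by = 2)),  # 25-29 right approach
    c(106, 104),                                # 30 right intersection
    rbind(c(110, 110), c(114, 118), c(116, 126), c(116, 134)), # 31-34 -> G1
    rbind(c(100, 112), c(96, 120), c(94, 128), c(92, 134))     # 35-38 -> G2
  )
  z$x <- xy[, 1]
  z$y <- xy[, 2]

  seg3 <- z$segment
  seg3[seg3 %in% c("home", "decision")] <- "stem"
  seg3[z$zone_id %in% 11:24] <- "left"
  seg3[z$zone_id %in% 25:38] <- "right"
  z$segment3 <- seg3

  z$branch <- NA_character_
  z$branch[z$zone_id %in% 11:24] <- "L"
  z$branch[z$zone_id %in% 25:38] <- "R"

  # linearized position: H=1, stem 2-10, D=11, approach 12-16, intersection
  # 17, arm 18-20, goal 21; left/right (and both goal arms) are equivalents
  lin <- integer(39)
  lin[1] <- 1L
  lin[2:10] <- 2:10
  lin[11] <- 11L
  lin[12:16] <- 12:16   # left approach
  lin[17] <- 17L
  lin[18:21] <- 18:21   # arm to G4
  lin[22:25] <- 18:21   # arm to G3
  lin[26:30] <- 12:16   # right approach
  lin[31] <- 17L
  lin[32:35] <- 18:21   # arm to G1
  lin[36:39] <- 18:21   # arm to G2
  z$linear_pos <- lin

  chain <- function(ids) {
    cbind(ids[-length(ids)], ids[-1])
  }
  edges <- rbind(
    chain(0:10),          # H - stem - D
    chain(c(10, 11:16)),  # D - left approach - intersection
    chain(c(16, 17:20)),  # -> G4
    chain(c(16, 21:24)),  # -> G3
    chain(c(10, 25:30)),  # D - right approach - intersection
    chain(c(30, 31:34)),  # -> G1
    chain(c(30, 35:38))   # -> G2
  )
  adjacency <- vector("list", 39)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adjacency[[a + 1]] <- c(adjacency[[a + 1]], b)
    adjacency[[b + 1]] <- c(adjacency[[b + 1]], a)
  }
  adjacency <- lapply(adjacency, function(v) sort(unique(as.integer(v))))

  structure(
    list(zones = z, adjacency = adjacency, bounds = c(0, 120, 0, 140)),
    class = "zone_map"
  )
}

#' Look up the well zone ids of a zone map
#' @param zones a `zone_map`
#' @return named integer vector, names H, D, G1..G4
#' @export
well_zones <- function(zones) {
  w <- zones$zones[!is.na(zones$zones$well), ]
  stats::setNames(w$zone_id, w$well)
}

#' Branch of a goal well ("L" or "R")
#' @param well character vector of well labels (G1..G4)
#' @return character vector of branch labels
#' @export
goal_branch <- function(well) {
  out <- rep(NA_character_, length(well))
  out[well %in% c("G1", "G2")] <- "R"
  out[well %in% c("G3", "G4")] <- "L"
  out
}

#' Assign tracking samples to maze zones
#'
#' Nearest-centroid assignment constrained to the adjacency graph: each
#' sample is assigned to the nearest zone among the previously assigned zone
#' and its neighbors, which enforces trajectory continuity and prevents
#' jumps across branches near the junctions. If the constrained nearest
#' centroid is farther than `fallback_dist`, the globally nearest zone is
#' used instead (e.g. after a tracking dropout). Samples outside the maze
#' bounding box (with `margin` cm of slack) get the sentinel `NA`.
#'
#' @param tracking data.frame with columns `x`, `y` (cm)
#' @param zones a `zone_map` from [treemaze_zones()]
#' @param fallback_dist cm; constrained assignments farther than this fall
#'   back to the global nearest centroid
#' @param margin cm of slack around the bounding box before a sample is
#'   declared out of bounds
#' @return integer vector of zone_ids (0..38), `NA` for out-of-bounds samples
#' @export
assign_zones <- function(tracking, zones, fallback_dist = 20, margin = 5) {
  if (is.null(tracking) || nrow(tracking) == 0) {
    stop("assign_zones: empty tracking")
  }
  zx <- zones$zones$x
  zy <- zones$zones$y
  b <- zones$bounds
  n <- nrow(tracking)
  out <- rep(NA_integer_, n)
  oob <- tracking$x < b[1] - margin | tracking$x > b[2] + margin |
    tracking$y < b[3] - margin | tracking$y > b[4] + margin
  prev <- NA_integer_
  for (i in seq_len(n)) {
    if (oob[i]) {
      next
    }
    d2 <- (zx - tracking$x[i])^2 + (zy - tracking$y[i])^2
    if (is.na(prev)) {
      z <- which.min(d2) - 1L
    } else {
      cand <- c(prev, zones$adjacency[[prev + 1]])
      zc <- cand[which.min(d2[cand + 1])]
      if (sqrt(d2[zc + 1]) > fallback_dist) {
        z <- which.min(d2) - 1L
      } else {
        z <- zc
      }
    }
    out[i] <- z
    prev <- z
  }
  out
}
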