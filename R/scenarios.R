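#' Deterministic task scenarios
#'
#' Versioned fixtures reproducing the topology of the simulated navigation
#' tasks. Three families are provided:
#'
#' * `fig1_abcde`, `fig1_abced`, `fig1_ebcda`, `fig1_bacde` — the five-feeder
#'   open-field task. A circular arena of radius 1.51 m carries 21 feeders on
#'   an Archimedean spiral; five of them are baited and labelled A-E. The
#'   ABCDE visit order is the efficient tour; the other three orders each
#'   share an efficient sub-path with ABCDE (ABC, BCD and CDE respectively)
#'   plus a long meandering detour. The baited spiral indices are fixed so
#'   that the ABCDE path is strictly the shortest of the four.
#' * `tmaze_abc`, `tmaze_abd` — a T-maze with start A, junction B, a near
#'   reward at C (short arm) and a far reward at D (long arm). The two
#'   sequences share the prefix A-B.
#' * `loop_left`, `loop_right`, `loop_outer_ccw` — a two-loop (figure-eight)
#'   maze. `loop_left` runs counter-clockwise around the left loop from the
#'   maze start MS via the central stem; `loop_right` runs clockwise around
#'   the right loop. `loop_outer_ccw` is the full counter-clockwise outer
#'   circuit used to probe shortcut generation; its right-hand side is only
#'   ever experienced in the opposite direction during training.
#'
#' The exact geometry (spiral pitch, arm lengths) is a documented convention
#' of this package; only the topology and the relative path lengths carry
#' scientific meaning.
#'
#' @param name Scenario name, one of the strings listed above.
#' @param reward_d Reward magnitude at feeder D in the T-maze scenarios
#'   (default 1; set 10 to model a ten-fold stronger reward).
#' @return A list with elements `arena` ([arena_config()]),
#'   `trajectory` ([trajectory()]) and `reward` (numeric reward signal).
#' @examples
#' sc <- scenario("fig1_abcde")
#' sc$trajectory
#' @export
scenario <- function(name = c("fig1_abcde", "fig1_abced", "fig1_ebcda",
                              "fig1_bacde", "tmaze_abc", "tmaze_abd",
                              "loop_left", "loop_right", "loop_outer_ccw"),
                     reward_d = 1) {
  name <- match.arg(name)
  if (startsWith(name, "fig1")) {
    arena <- spiral_feeders(21, arena_config("circular", radius_m = 1.51),
                            baited = c(A = 15, B = 5, C = 8, D = 10,
                                       E = 12))
    order <- toupper(strsplit(sub("fig1_", "", name), "")[[1]])
    traj <- make_trajectory(order, arena)
  } else if (startsWith(name, "tmaze")) {
    feeders <- rbind(
      feeder("A", 0, -0.75),
      feeder("B", 0, 0.05),
      feeder("C", -0.40, 0.05, baited = TRUE),
      feeder("D", 0.85, 0.05, baited = TRUE, reward_magnitude = reward_d))
    arena <- arena_config("rectangular", extent_m = c(2, 2),
                          feeders = feeders)
    order <- toupper(strsplit(sub("tmaze_", "", name), "")[[1]])
    traj <- make_trajectory(order, arena)
  } else {
    feeders <- rbind(
      feeder("MS", 0, -0.8), feeder("T2", 0, 0.8),
      feeder("TL", -0.8, 0.8), feeder("BL", -0.8, -0.8),
      feeder("TR", 0.8, 0.8), feeder("BR", 0.8, -0.8))
    arena <- arena_config("rectangular", extent_m = c(2, 2),
                          feeders = feeders)
    wp <- switch(name,
      loop_left = c("MS", "T2", "TL", "BL", "MS"),
      loop_right = c("MS", "T2", "TR", "BR", "MS"),
      loop_outer_ccw = c("MS", "BR", "TR", "TL", "BL", "MS"))
    traj <- make_trajectory(wp, arena)
  }
  list(arena = arena, trajectory = traj,
       reward = make_reward_signal(traj, arena))
}
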