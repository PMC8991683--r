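# Canonical obstacle sets for the four 20x20 foraging environments.
# Coordinates are (x, y), 0-indexed, y increasing upward. Obstacle cells are
# removed from the state graph entirely (no edges in or out), so actions that
# would enter them bounce the agent back to its current state.
#
# Only the four-rooms layout is pinned by a published state count (365
# available states); the separated-field and tunnel layouts are reconstructions
# of the depicted mazes: a single bottleneck gap at the top of a vertical wall,
# and a one-row corridor walled above and below but open at both ends.

grid_side <- 20L

layout_obstacles <- function(layout) {
  switch(layout,
    open_field = cbind(x = integer(0), y = integer(0)),
    separated_field = cbind(x = rep(10L, 14L), y = 0:13),
    four_rooms = {
      vertical <- cbind(x = 10L, y = 0:19)
      horizontal <- cbind(x = 0:19, y = 10L)
      wall <- unique(rbind(vertical, horizontal)) # (10,10) shared
      doors <- cbind(x = c(10L, 10L, 5L, 15L), y = c(5L, 15L, 10L, 10L))
      wall[!paste(wall[, 1], wall[, 2]) %in% paste(doors[, 1], doors[, 2]), ,
           drop = FALSE]
    },
    tunnel = cbind(x = rep(1:18, 2L), y = rep(c(9L, 11L), each = 18L)),
    stop("unknown layout: ", layout, call. = FALSE)
  )
}

layout_names <- c("open_field", "separated_field", "four_rooms", "tunnel")

# Default reward location, off-centre and non-obstacle in every layout.
default_reward_state <- c(14L, 14L)
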