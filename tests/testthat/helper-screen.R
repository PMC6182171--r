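# Memoised full screen on the default synthetic world: several
# acceptance-level checks share one run.
.screen_cache <- new.env(parent = emptyenv())

default_screen <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.screen_cache[[key]])) {
    world <- generate_world(world_config(seed = seed))
    result <- erosion_screen(world = world, seed = seed)
    .screen_cache[[key]] <- list(world = world, result = result,
                                 recovery = evaluate_recovery(result, world))
  }
  .screen_cache[[key]]
}
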