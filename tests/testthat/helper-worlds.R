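# Shared builders for small in-code fixtures.

tiny_library <- function() {
  gene_set_library(list(
    PW1 = list(description = "d1", members = c("A1", "A2", "A3")),
    PW2 = list(description = "d2", members = c("A3", "A4")),
    PW3 = list(description = "d3", members = c("B1", "B2", "B3", "B4"))
  ))
}

tiny_annotation <- function() {
  hallmark_annotation(list(
    PW1 = "cellular_senescence",
    PW2 = c("cellular_senescence", "chronic_inflammation"),
    PW3 = "chronic_inflammation"
  ))
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A deterministic micro screen used by io/report tests.
example_screen <- function() {
  w <- worked_example_world()
  hallmark_screen(list(w$targets), w$library, w$annotations, w$config)
}
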