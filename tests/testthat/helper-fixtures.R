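# Tiny graphs with known degree structure, built in code.

triangle_graph <- function() {
  molecular_graph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
}

star_graph <- function(leaves = 4) {
  molecular_graph(data.frame(from = rep("hub", leaves),
                             to = paste0("leaf", seq_len(leaves))))
}

path_graph <- function(n = 3) {
  v <- paste0("p", seq_len(n))
  molecular_graph(data.frame(from = v[-n], to = v[-1]))
}

# rational schemes (everything except ABS)
rational_schemes <- function() setdiff(scheme_names(), "ABS")

write_edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
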