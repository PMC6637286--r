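# Branching-tree profiles for the cine-angiography phantom. Each inflow
# trunk (generation 1) fans into `children` generation-2 vessels, each of
# which fans into `children` generation-3 vessels. Pruning removes at most
# one child per junction (keeping every junction of degree >= 3) so that
# expected per-generation losses match the configured fractions; the
# hyperoxia values encode the reported reductions (-18% generation 2,
# -21% generation 3).
defaults:
  n_trees: 4
  children: 3
  depth: 3
profiles:
  air_vehicle:
    prune_g2: 0.0
    prune_g3: 0.0
  hyperoxia_vehicle:
    prune_g2: 0.18
    prune_g3: 0.21
  hyperoxia_il1ra:
    prune_g2: 0.04
    prune_g3: 0.05
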