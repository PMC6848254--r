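# Two-node change detector driven by a prolonged 2-s step stimulus under
# the NMDA-antagonist condition; inter-node gains from the Off solution set.
network:
  preset: two_node
  w21: [13.5, 27, 27, 0]
  w12: [27, 27, 0, 0]
protocol:
  type: step
  onset: 0
  offset: 2
condition: III
solver:
  dt: 0.0005
  settle: 2
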