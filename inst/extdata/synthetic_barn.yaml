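# Synthetic free-stall barn of realistic geometry: 9.8 m x 39 m usable floor
# (y runs 3..42), 1 m mapping grid, 10 receiving stations at 3.5-4.5 m height
# in two columns (~8-10 m neighbour spacing), cubicle partition walls, a
# milking-robot enclosure, and labelled zones. The layout is synthetic: it is
# generated for simulation and does not reproduce any particular real barn.
name: synthetic_barn
extents:
  xmin: 0.0
  xmax: 9.8
  ymin: 3.0
  ymax: 42.0
resolution: 1.0
tag_height: 1.5
stations:
  - {id: S01, x: 1.5, "y": 6.0, z: 4.0}
  - {id: S02, x: 1.5, "y": 14.0, z: 3.5}
  - {id: S03, x: 1.5, "y": 22.0, z: 4.5}
  - {id: S04, x: 1.5, "y": 30.0, z: 4.0}
  - {id: S05, x: 1.5, "y": 38.0, z: 3.5}
  - {id: S06, x: 8.3, "y": 6.0, z: 4.5}
  - {id: S07, x: 8.3, "y": 14.0, z: 4.0}
  - {id: S08, x: 8.3, "y": 22.0, z: 3.5}
  - {id: S09, x: 8.3, "y": 30.0, z: 4.5}
  - {id: S10, x: 8.3, "y": 38.0, z: 4.0}
obstacles:
  # cubicle partition walls flanking the central alley
  - [[3.4, 6.0], [3.4, 20.0]]
  - [[6.4, 6.0], [6.4, 20.0]]
  # milking-robot enclosure (closed; interior excluded from the grid)
  - [[0.0, 37.5], [3.0, 37.5], [3.0, 41.5], [0.0, 41.5], [0.0, 37.5]]
zones:
  feeding:
    [[7.9, 2.9], [9.9, 2.9], [9.9, 42.1], [7.9, 42.1], [7.9, 2.9]]
  cubicles:
    [[-0.1, 5.5], [3.4, 5.5], [3.4, 20.5], [-0.1, 20.5], [-0.1, 5.5]]
  robot:
    [[-0.1, 37.4], [3.1, 37.4], [3.1, 41.6], [-0.1, 41.6], [-0.1, 37.4]]
  waiting_yard:
    [[3.4, 35.5], [7.9, 35.5], [7.9, 42.1], [3.4, 42.1], [3.4, 35.5]]
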