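{
  "schema_version": "1.0",
  "overall_thickness": 42,
  "half_width": 50,
  "depth": 80,
  "test_plane_z": 21,
  "chest_wall_plane": 0,
  "gauges": [
    {
      "n_steps": 12,
      "step_increment": 0.5,
      "lateral_position": -35,
      "width": 4,
      "z_center": 21,
      "thickness": 1,
      "contrast": 1,
      "id": "gauge1"
    },
    {
      "n_steps": 12,
      "step_increment": 0.5,
      "lateral_position": -12,
      "width": 4,
      "z_center": 21,
      "thickness": 1,
      "contrast": 1,
      "id": "gauge2"
    },
    {
      "n_steps": 12,
      "step_increment": 0.5,
      "lateral_position": 12,
      "width": 4,
      "z_center": 21,
      "thickness": 1,
      "contrast": 1,
      "id": "gauge3"
    },
    {
      "n_steps": 12,
      "step_increment": 0.5,
      "lateral_position": 35,
      "width": 4,
      "z_center": 21,
      "thickness": 1,
      "contrast": 1,
      "id": "gauge4"
    }
  ],
  "ramps": [
    {
      "bead_diameter": 0.18,
      "vertical_spacing": 0.25,
      "total_rise": 10,
      "x_start": -45,
      "x_pitch": 1,
      "y_lower": 24.5,
      "y_upper": 25.5,
      "z_base": 16,
      "direction": 1,
      "side": "left",
      "contrast": 10
    },
    {
      "bead_diameter": 0.18,
      "vertical_spacing": 0.25,
      "total_rise": 10,
      "x_start": 5,
      "x_pitch": 1,
      "y_lower": 24.5,
      "y_upper": 25.5,
      "z_base": 26,
      "direction": -1,
      "side": "right",
      "contrast": 10
    }
  ],
  "z_beads": [
    {
      "x": -12,
      "y": 14,
      "z": 11,
      "diameter": 5,
      "contrast": 1
    },
    {
      "x": 0,
      "y": 14,
      "z": 21,
      "diameter": 5,
      "contrast": 1
    },
    {
      "x": 12,
      "y": 14,
      "z": 31,
      "diameter": 5,
      "contrast": 1
    }
  ],
  "low_contrast_spheres": [
    {
      "x": -2.952,
      "y": 66.742,
      "z": 21,
      "diameter": 0.8,
      "contrast": 0.02
    },
    {
      "x": 15.975,
      "y": 55.814,
      "z": 21,
      "diameter": 1,
      "contrast": 0.02
    },
    {
      "x": 8.5,
      "y": 64.722,
      "z": 21,
      "diameter": 1.5,
      "contrast": 0.02
    },
    {
      "x": -13.023,
      "y": 60.927,
      "z": 21,
      "diameter": 2,
      "contrast": 0.02
    },
    {
      "x": 15.975,
      "y": 44.186,
      "z": 21,
      "diameter": 3,
      "contrast": 0.02
    },
    {
      "x": -17,
      "y": 50,
      "z": 21,
      "diameter": 4,
      "contrast": 0.02
    },
    {
      "x": 8.5,
      "y": 35.278,
      "z": 21,
      "diameter": 6,
      "contrast": 0.02
    },
    {
      "x": -13.023,
      "y": 39.073,
      "z": 21,
      "diameter": 8,
      "contrast": 0.02
    },
    {
      "x": -2.952,
      "y": 33.258,
      "z": 21,
      "diameter": 10,
      "contrast": 0.02
    }
  ],
  "al_square": {
    "center": [0, 50, 21],
    "side": 10,
    "thickness": 1,
    "contrast": 0.2
  },
  "alignment_markers": [
    {
      "x": -44,
      "y": 8,
      "z": 21,
      "diameter": 3,
      "contrast": 2
    },
    {
      "x": 44,
      "y": 8,
      "z": 21,
      "diameter": 3,
      "contrast": 2
    },
    {
      "x": -44,
      "y": 72,
      "z": 21,
      "diameter": 3,
      "contrast": 2
    },
    {
      "x": 44,
      "y": 72,
      "z": 21,
      "diameter": 3,
      "contrast": 2
    }
  ],
  "background_value": 1
}
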