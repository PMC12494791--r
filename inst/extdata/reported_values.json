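{
  "comment": "Previously reported closed forms, numeric tables (n = 1..10) and logarithmic-model statistics for the polyester and polycarbonate chain families, transcribed as published. Entropy forms are parameterized as ENT(n) = ln I(n) - S(n)/I(n) with I, S linear in n; the ReZG1 entropy forms were published as ln(I) + c + d/n and are stored that way.",
  "closed_forms": {
    "polyester": {
      "index": {
        "M1": {"a": 122, "b": -8},
        "M2": {"a": 150, "b": -14},
        "ReZG1": {"a": 22, "b": 0},
        "ReZG2": {"a": 26.766, "b": -2.116},
        "ReZG3": {"a": 868, "b": -88},
        "ABC": {"a": 17.137, "b": 0.0617},
        "GA": {"a": 20.287, "b": -1.066}
      },
      "entropy": {
        "M1": {"I": {"a": 122, "b": -8}, "S": {"a": 205.6953, "b": -15.7033}},
        "M2": {"I": {"a": 150, "b": -14}, "S": {"a": 299.2895, "b": -32.7749}},
        "ReZG1": {"I": {"a": 22, "b": 0}, "c": -0.00785, "d": -0.04498},
        "ReZG2": {"I": {"a": 26.766, "b": -2.116}, "S": {"a": 5.448, "b": -1.2248}},
        "ReZG3": {"I": {"a": 868, "b": -88}, "S": {"a": 3338.58, "b": -360.38}},
        "ABC": {"I": {"a": 17.137, "b": 0.0617}, "S": {"a": -4.9345, "b": 0.3113}},
        "GA": {"I": {"a": 20.287, "b": -1.066}, "S": {"a": -1.6125, "b": -0.0539}}
      }
    },
    "polycarbonate": {
      "index": {
        "M1": {"a": 164, "b": -8},
        "M2": {"a": 205, "b": -12},
        "ReZG1": {"a": 29, "b": 0},
        "ReZG2": {"a": 36.578, "b": -1.93},
        "ReZG3": {"a": 1168, "b": -68},
        "ABC": {"a": 22.865, "b": -0.707},
        "GA": {"a": 30.027, "b": -0.996}
      },
      "entropy": {
        "M1": {"I": {"a": 164, "b": -8}, "S": {"a": 311.1514, "b": -15.3006}},
        "M2": {"I": {"a": 205, "b": -12}, "S": {"a": 413.856, "b": -25.3202}},
        "ReZG1": {"I": {"a": 29, "b": 0}, "c": 0.01958, "d": -0.03669},
        "ReZG2": {"I": {"a": 36.578, "b": -1.93}, "S": {"a": 7.8702, "b": -0.9267}},
        "ReZG3": {"I": {"a": 1168, "b": -68}, "S": {"a": 4692.52, "b": -46.924}},
        "ABC": {"I": {"a": 22.865, "b": -0.707}, "S": {"a": -6.8133, "b": 0.2451}},
        "GA": {"I": {"a": 30.027, "b": -0.996}, "S": {"a": -1.8743, "b": 0.0045}}
      }
    }
  },
  "tables": {
    "polyester": {
      "indices": {
        "M1": [114, 236, 358, 480, 602, 724, 846, 968, 1090, 1212],
        "M2": [136, 286, 436, 586, 736, 886, 1036, 1186, 1336, 1486],
        "ReZG1": [22, 44, 66, 88, 110, 132, 154, 176, 198, 220],
        "ReZG2": [24.65, 51.416, 78.182, 104.948, 131.714, 158.48, 185.246, 212.012, 238.778, 265.544],
        "ReZG3": [780, 1648, 2516, 3384, 4252, 5120, 5988, 6856, 7724, 8592],
        "ABC": [17.198, 34.3357, 51.4727, 68.6097, 85.7467, 102.8837, 120.0207, 137.1577, 154.2947, 171.4317],
        "GA": [19.221, 39.508, 59.795, 80.082, 100.369, 120.656, 140.943, 161.23, 181.517, 201.804]
      },
      "entropies": {
        "M1": [3.07, 3.787, 4.201, 4.492, 4.718, 4.902, 5.057, 5.191, 5.310, 5.416],
        "M2": [2.952, 3.677, 4.093, 4.386, 4.612, 4.796, 4.952, 5.087, 5.206, 5.311],
        "ReZG1": [3.038, 3.753, 4.166, 4.458, 4.683, 4.867, 5.022, 5.157, 5.275, 5.381],
        "ReZG2": [3.033, 3.751, 4.165, 4.457, 4.682, 4.866, 5.021, 5.156, 5.275, 5.380],
        "ReZG3": [2.841, 3.574, 3.992, 4.287, 4.514, 4.698, 4.854, 4.989, 5.108, 5.214],
        "ABC": [3.114, 3.815, 4.223, 4.512, 4.736, 4.918, 5.073, 5.207, 5.325, 5.430],
        "GA": [3.042, 3.759, 4.172, 4.4643, 4.689, 4.873, 5.028, 5.163, 5.281, 5.387]
      }
    },
    "polycarbonate": {
      "indices": {
        "M1": [156, 320, 484, 648, 812, 976, 1140, 1304, 1468, 1632],
        "M2": [193, 398, 603, 808, 1013, 1218, 1423, 1628, 1833, 2038],
        "ReZG1": [29, 58, 87, 116, 145, 174, 203, 232, 261, 290],
        "ReZG2": [34.65, 71.226, 107.804, 144.382, 180.96, 217.538, 254.116, 290.694, 327.272, 363.85],
        "ReZG3": [1100, 2268, 3436, 4604, 5772, 6940, 8108, 9276, 10444, 11612],
        "ABC": [22.158, 45.023, 67.888, 90.753, 113.618, 136.483, 159.348, 182.213, 205.078, 227.943],
        "GA": [29.031, 59.058, 89.085, 119.112, 149.139, 179.166, 209.193, 239.22, 269.247, 299.274]
      },
      "entropies": {
        "M1": [3.153, 3.871, 4.285, 4.577, 4.802, 4.986, 5.142, 5.276, 5.394, 5.500],
        "M2": [3.249, 3.970, 4.384, 4.677, 4.902, 5.087, 5.242, 5.376, 5.495, 5.601],
        "ReZG1": [3.350, 4.061, 4.473, 4.764, 4.988, 5.172, 5.327, 5.461, 5.580, 5.685],
        "ReZG2": [3.444, 4.058, 4.470, 4.761, 4.985, 5.170, 5.325, 5.459, 5.577, 5.683],
        "ReZG3": [2.779, 3.609, 4.058, 4.367, 4.604, 4.794, 4.955, 5.093, 5.214, 5.322],
        "ABC": [3.394, 4.104, 4.515, 4.805, 5.030, 5.213, 5.368, 5.502, 5.621, 5.726],
        "GA": [3.432, 4.142, 4.552, 4.843, 5.068, 5.251, 5.406, 5.540, 5.658, 5.764]
      }
    }
  },
  "regressions": {
    "polyester": {
      "M1": {"a": 0.9931, "b": -1.6369, "R": 0.9999, "R2": 0.9999, "SE": 0.0021, "F": 243491.042, "p": 4.684e-22},
      "M2": {"a": 0.9877, "b": -1.7058, "R": 0.9999, "R2": 0.9999, "SE": 0.0034, "F": 45794.791, "p": 2.835e-20},
      "ReZG1": {"a": 1.0162, "b": -0.096, "R": 0.9999, "R2": 0.9999, "SE": 0.0042, "F": 99577.556, "p": 1.39e-19},
      "ReZG2": {"a": 0.9886, "b": -0.1407, "R": 0.9999, "R2": 0.9999, "SE": 0.0034, "F": 85590.922, "p": 2.014e-20},
      "ReZG3": {"a": 0.99, "b": -3.7565, "R": 0.9999, "R2": 0.9999, "SE": 0.0026, "F": 709494.075, "p": 5.526e-21},
      "ABC": {"a": 0.2536, "b": 1.0067, "R": 0.9999, "R2": 0.9999, "SE": 0.0011, "F": 344208.171, "p": 3.43e-22},
      "GA": {"a": 0.9975, "b": 0.0921, "R": 0.9999, "R2": 0.9999, "SE": 0.0007, "F": 9693762.702, "p": 1.268e-25}
    },
    "polycarbonate": {
      "M1": {"a": 0.9998, "b": -1.8959, "R": 0.999, "R2": 0.999, "SE": 0.0002, "F": 58301679.59, "p": 9.693e-29},
      "M2": {"a": 0.998, "b": -2.0041, "R": 0.9999, "R2": 0.9999, "SE": 0.0006, "F": 12140884.549, "p": 5.154e-26},
      "ReZG1": {"a": 1.013, "b": -0.0551, "R": 0.9999, "R2": 0.9999, "SE": 0.0034, "F": 14071.096, "p": 3.809e-20},
      "ReZG2": {"a": 0.9992, "b": -0.1006, "R": 0.9999, "R2": 0.9999, "SE": 0.0013, "F": 489156.262, "p": 7.556e-24},
      "ReZG3": {"a": 1.0724, "b": -4.6958, "R": 0.9997, "R2": 0.9994, "SE": 0.0201, "F": 4504.34, "p": 2.525e-14},
      "ABC": {"a": 1.0004, "b": 0.2949, "R": 0.9999, "R2": 0.9999, "SE": 0.0003, "F": 41206416.161, "p": 3.884e-28},
      "GA": {"a": 0.651, "b": 0.099, "R": 0.9999, "R2": 0.9999, "SE": 0.0002, "F": 62921885.127, "p": 7.145e-29}
    }
  },
  "verified": {
    "index_columns": {
      "polyester": ["M1", "M2", "ReZG1", "ReZG2", "ReZG3"],
      "polycarbonate": ["M1", "M2", "ReZG1", "ReZG2", "ABC"]
    },
    "entropy_columns": {
      "polyester": ["M1", "M2", "ReZG1", "ReZG2", "ReZG3"],
      "polycarbonate": ["ReZG1", "ABC"]
    },
    "regressions": {
      "polyester": ["M1", "M2", "ReZG1", "ReZG2", "ReZG3"],
      "polycarbonate": ["M2", "ReZG1", "ABC"]
    }
  }
}
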