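"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,26.48,26.39,27.03,28.47,35.36,41.1,43.52,53.01,58.25,65.23,69.99,76.82,81.93,82.86,89.54,89.71,92.69,29.14,33.97,38.56,44.48,49.48,65.49,70.68,76.68,80.12,85.53,58.54,57.96,58.89,57.65,51.58,52.74,58.36,62.92,67.26,47.75,42.42,37.62,33.17,37.48,42.18,82.81,78.24,73.27,70.48,72.22,79.8,71.58,70.35,66.12,57.88,48.42,45.3,44.32,46.58,50.86,57.61,66.38,71.51,65.96,65.12,56.62,49.1,49.47,51.1,58.38,64,53.05,59.05,68.11,74.65,80.45,84.64,87.95,90.97,91.73,90.45,89.59,85.67,80.95,72.82,66.72,58.95,52.89,33.38,30.06,33.54,31.07,33.65,33.45,30.78,30.06,33.07,32.66,39.39,46.79,50.24,57.1,58.74,61.14,61.2,60.13,58.97,40.79,37.62,40.3,38.64,43.4,41.62,41.64,38.34,38.2,41.71,42.94,42.51,72.01,67.58,64.89,63.51,65.18,67.29,74.85,75.18,78.81,81.88,76.26,73.07,72.27,68.1,68.37,68.79,73.22,75.18,76,73.38
2,25.93,26.94,27.36,30.65,34.02,40.71,46.61,53.17,57.06,64.92,70.97,77.31,81.65,87.98,86.5,87.93,91.43,30.55,35.93,39.49,44.72,48.04,66.22,70.15,76.43,79.94,86.64,57.36,58.48,59.22,57.81,52.68,52.65,57.51,62.59,67.55,45.66,41.64,38.2,34.68,36.71,43.26,84.05,79.4,72.49,69.62,72.9,79.62,71.93,72.04,67.67,57.44,49.73,46.81,43.44,44.2,49.36,59.02,66.35,69.35,67.06,64.69,58.96,50.26,50.06,52.96,58.16,63.9,50.74,60.02,66.93,74.25,78.37,84.9,89.11,91.6,89.82,89.56,89.56,83.77,80.89,73.64,66.21,58.65,53.67,33.09,31.38,32.37,32.59,33,34.15,32.15,31.08,30.93,32.8,41.33,44.98,51.03,53.36,59.35,58.91,60.33,59.58,60.24,41.25,38.18,38.17,40.18,43.18,42.31,39.52,40.23,36.76,40.42,43.16,43.86,73.03,67.92,66.69,65.08,65.22,65.08,72.16,75.83,80.07,79.05,77.23,75.59,72.88,67.42,68.58,69.5,72.56,74.68,74.95,74.32
3,25.06,28.28,28.52,31.14,37.06,41.44,44.6,53.86,58.51,65.41,73.21,77.6,83.43,85.75,87.5,90.72,94.31,30.5,36.85,39.95,44.72,50.92,67.59,71.22,77.99,81.15,85.93,57.62,60.74,60.47,57.37,51.18,53.99,57.98,63.43,66.82,47.61,44.02,37.4,31.66,35.88,43.02,83.73,81.08,72.56,72.55,73.36,80.47,70.52,71.67,66.45,59.75,51.1,47.66,44.79,43.9,51.95,57.64,69.26,71.03,68.42,62.83,58.2,52.25,49.29,54.84,58.5,64.62,49.53,56.8,67.2,72.36,76.99,83.73,86.75,87.59,89.32,89.4,86.77,84.51,80.64,72.3,67.08,58.88,51.75,30.65,30.75,31.01,28.59,31.17,31.84,30.56,28.22,30.04,31.36,38.18,43.53,50.09,52.59,57.6,59,58.06,59.41,57.01,39.14,37.09,35.11,38.94,40.69,40.01,37.57,35.96,37.67,40.32,41.21,39.36,69.85,65.14,64,63.15,64.78,67.46,70.97,74.14,77.66,77.93,78.52,73.4,71.41,68.31,66.84,69.9,69.4,73.84,71.13,74.42
4,24.7,23.99,25.46,28.74,33.23,37.91,43.2,49.87,55.12,65.91,68.83,72.59,78.52,84.32,84.73,89.25,90.04,27.79,33.61,37.81,42.38,47.15,65.18,70.88,73.95,78.63,84.78,56.41,58.34,54.79,56.97,48.63,52.87,54.79,61.06,65.89,44.7,39.91,34.3,30.85,34.33,40.39,82.45,77.71,71.29,67.8,72.12,78.09,70.13,68.56,63.87,57.45,48.28,43.58,43.32,41.26,51.11,55.25,66.13,68.15,64.76,61.72,56.81,49.48,47.01,49.71,54.72,61.68,48.56,56.71,66.15,72.03,76.8,83.03,88.51,90.52,89.14,89.23,88.13,85,79.04,72.13,63.71,58.49,51.45,29.61,28.39,28.46,28.72,31.18,32.18,31.02,28.51,29.84,29.13,37.23,44.34,49.31,54,56.39,58.32,59.62,58.47,57.67,38.27,35.7,36.87,37.25,41.68,39.77,40.22,37.83,38.66,37.95,40.64,42.27,72.73,66.25,64.35,62.51,62.16,65.88,67.25,73.32,76.18,78.9,77.23,71.76,70.37,65.97,65.23,65.53,70.77,70.57,73.98,70.68
5,23.21,22.47,21.76,28.48,30.23,35.97,40,47.2,55.22,62.55,68.5,73.01,77.74,82.77,82.62,87.57,88.76,28.09,33.08,35.64,43.06,47.31,64.97,68.91,74.16,77.61,84.19,55.05,55.2,55.84,55.06,48.51,50.67,53.93,59.38,63.99,43.47,42.25,35.97,30.13,34.61,40.44,80.31,76.23,69.84,67.5,69.41,77.07,67,66.1,60.44,54.9,46.87,42.13,41.58,43.27,47.65,56.13,62.4,67.03,63.87,61.72,54.43,48.4,43.97,49.37,54.17,61.78,47.64,56.9,64.96,71.41,77.9,81.02,85.61,88.91,87.79,89.37,83.83,82.1,79.33,69.07,63.98,56.95,49.62,29.12,27.44,28.38,29.33,28.82,30.19,28.4,28.62,28.62,29.75,39.28,41.07,48.03,52.09,55.27,55.95,58.5,57.42,55.64,37.5,35.25,34.76,36.81,41.23,37.06,37.83,33.89,33.58,39.07,39.82,39.18,70.84,64.14,62.25,62.07,63.04,63.91,67.95,71.82,77.2,77.92,75.24,73.14,67.85,63.88,66.52,65.14,69.47,71.65,72.81,70.25
6,20.78,23.82,23.58,26.86,32.04,37.86,43.01,48.51,54.75,63.04,69.35,73.46,77.96,80.75,84.68,89.1,88.8,28.84,32.72,35.83,41.71,44.7,65.07,68.16,73.99,78.59,83.67,54.79,54.25,56.58,54.28,49.08,50.67,54.36,60.53,63.36,43.69,40.61,33.78,29.57,34.23,39.36,80.75,75.14,70.24,67.89,69.77,75.63,67.61,67.65,64.64,55.08,46.71,40.69,40.85,41.56,47.4,54.14,63.42,66.74,64.97,61.08,53.55,48.02,45.87,51.1,54.15,59.92,50.49,57.81,67.23,74.59,78.22,83.77,84.97,89.06,88.82,89.39,89.49,84.38,79.79,71.53,65.82,59.38,51.05,33.17,29.71,29.31,30.72,32.37,32.23,30.32,29.51,30.74,33.53,39.6,43.74,51.54,53.51,57.53,59,59.85,62.4,59.31,40.45,38.21,34.8,39.12,42.67,41.76,38.8,36.62,37.66,38.91,43.07,40.34,72.88,66.37,65.74,63.33,66.41,67.33,71.86,74.53,77.31,79.36,79.06,74.47,70.98,68.17,69.21,70.11,71.64,75.6,75.49,74.77
7,21.58,23.1,22.98,25.23,30.82,38.12,39.82,46.3,57.41,61.95,67.84,71.32,77.02,84.54,84.74,87.58,88.04,27.7,32.6,38.65,42.44,46.16,65.23,67.64,74.77,76.9,83.01,53.8,54.66,55.29,55.33,48.24,49.99,53.48,59.68,62.96,44.81,42.22,33.12,30.12,34.1,38.68,79.5,75.69,68.56,66.69,68.59,76.1,67.42,67.26,63.96,54.61,48,42.87,42.65,41.83,48.32,56.04,63.69,67.26,63.32,63,56.16,48.71,45.43,47.99,54.97,62.28,51.82,57.44,67.25,74.61,76.04,83.1,86.58,89.34,90.99,90.13,89.79,85.22,81.34,72.66,67.22,57.97,53.73,30.69,31.04,28.68,29.72,31.18,32.33,32.81,29.36,29.98,33.98,37.89,44.1,49.34,55.38,57.97,58.16,59.2,59.65,56.99,40.12,37.3,39.3,39.91,42.74,41.4,42.47,37.58,37.29,40.24,42.59,40.3,70.5,65.73,63.29,62.59,61.86,65.88,72.56,74.44,77.75,78.61,75.53,72.57,71.58,68.31,66.91,67.03,70.28,72.97,73.52,72.47
8,22.31,23.45,23.46,26.01,30.23,39.08,41.29,47.13,52.55,62.75,68.76,72.15,77.87,83,83.41,87.29,87.16,27.35,30.92,36.25,43.73,45.29,64.28,69.94,72.03,78.86,83.02,54.26,52.78,55.62,52.12,46.76,50.58,53.91,58.15,62.21,42.12,39.36,30.81,29.3,33.58,38.68,80.79,74.95,69.22,66.12,70.75,75.67,68.44,68.4,62.84,55.98,46.2,43.09,41.19,41.35,48.87,57.01,62.4,65.46,63.3,60.99,55.52,48.27,45.88,49.97,53.72,61.02,53.24,59.51,67.21,74.75,79.85,84.29,87.92,91.61,92.47,90.72,88.85,85.47,80.5,73.05,67.1,60.1,54.53,35.13,29.74,31.68,31.59,35.26,34.6,33.02,29.81,31.33,33.38,41.39,45.96,50.65,57.17,59.7,61.85,61.47,60.21,60.75,39.72,39.92,38.76,40.8,42.51,43.58,40.47,38.17,39.38,39.91,43.32,42.83,72.63,68.17,66.96,64.14,63.85,69.28,72.18,75.58,78.08,79.11,78.69,75.28,73.37,68.16,67.18,68.21,72.62,73.36,76.32,74.6
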