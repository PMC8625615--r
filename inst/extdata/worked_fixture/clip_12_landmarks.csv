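"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,17.26,20.77,22.69,24.8,31.55,35.71,43.62,49.84,56.77,64.25,68.02,76.62,82.82,86.81,91.23,92.28,94.78,23.6,31.68,36.44,41.48,46.5,65.84,72.56,74.33,82.67,88.25,55.11,56.85,57.12,59.92,49.16,53.46,57.93,59.73,65.92,44.35,39.86,33.95,28.94,31,40.37,82.38,79.93,73.24,69.44,71.96,80.69,72.43,70.53,65.49,54.8,48.61,41.34,39.04,41.9,49.33,55.95,65.39,72.05,68.34,66.39,58.38,48.75,45.49,50.38,56.91,61.83,51.73,60.79,69.76,77.37,86.36,87.82,92.25,95.65,95.93,95.51,93.04,88.98,84.19,76.13,68.67,59.35,51.94,29.88,29.28,30.41,28.83,30.7,32.83,27.94,28.62,30.99,31.06,39.14,45.27,48.62,58.06,60.1,62.1,63.48,61.31,59.61,41.26,37.88,37.1,37.29,39.46,41.84,40.96,37.25,37.23,39.37,42.09,41.27,77.29,71.49,71.2,68.87,71.27,75.54,80.47,82.51,83.44,87.75,84.91,82.87,77.13,78.08,73.39,77.04,78.83,79.62,80.78,82.76
2,23.52,22.19,26.33,26.91,34.14,37.23,47.47,53.19,58.11,69.62,73.39,80.26,84.75,91.36,92.4,96.11,97.57,27.71,33.37,38.09,44.07,49.24,69.49,75.21,78.54,86.09,90.01,59.65,56.73,57.96,59.54,48.97,54.01,59.71,61.99,67.56,48.47,42.44,34.95,32.55,36.93,41.31,86.77,82.81,76.56,72.94,77.94,83.77,74.57,73.17,66.48,60.61,51.27,45.15,43.18,44.21,50.73,59.46,67.52,73.82,69.75,67.12,60.52,52.25,49.42,51.27,59.46,65.77,49.97,59.53,68.66,74.73,82.47,85.79,90.05,95.46,93.77,93.31,91.42,90.6,80.88,73.8,67.02,57.98,50.41,30.97,27.65,28.01,29.55,31.27,31.11,26.37,28.08,29.31,29.19,39.56,44.1,49.36,54.82,59.28,60.65,60.84,58.7,60.11,38.83,35.63,35.52,37.53,41.54,43.11,38.56,35.25,35.48,39.57,41.24,40.57,74.88,69.96,70.61,69.16,71.4,73.27,76.3,82.82,83,86.69,84.28,81.66,75.62,73.82,74.74,76.87,76.73,82.04,82.14,79.75
3,17.31,17.53,19.84,23.85,29.14,34.71,40.82,47.41,52.71,62.09,69.78,74.28,81.54,83.75,87.46,90.15,89.51,23.07,27.87,32.46,39.06,45.1,64.36,71.04,73.95,79.13,85.47,56.04,54.07,53.82,55.58,45.76,49.32,54.51,58.01,62.13,41.54,36.21,30.71,26.45,28.7,36.4,80.79,78.59,70.55,68.89,70.49,79.66,72.81,68.88,62.82,53.9,47.05,39.61,37.32,40.23,47.9,53.21,61.48,70.01,65.58,60.98,55.52,46.18,43,46.23,53.32,59.4,47.78,59.33,68.99,78.25,80.76,90.54,91.75,96.57,94.61,96.2,92.33,89.16,82.15,74.14,66.94,57.78,51.46,28.9,27.88,28.57,31.1,29.13,28.91,26.46,27.81,27.91,28.92,41.08,42.42,48.77,55.07,59.15,60.5,60.1,59.57,58.82,39.67,36.14,36.54,37.97,40.31,40.11,38.42,35.87,34.77,39.97,39.88,41.57,77.95,71.85,69.55,68.95,72.2,73.34,75.08,82.74,83.95,87.52,85.03,81.96,76.8,73.77,74.17,76.35,77.11,79.96,81.62,80.47
4,18.05,18.19,21.69,23.27,28.46,34.02,39.95,48.34,53.45,62.01,67.18,74.5,82.46,88.26,88.46,92.04,90.86,24.04,29.68,36,38.5,43.32,66.14,71.27,73.85,81.96,86.3,55.57,54.16,55.31,57.26,47.83,51.57,55.46,60.47,64.56,42.26,37.06,31.47,30.59,30.23,38.8,81.42,77.72,72.38,69.13,71.05,79.64,70.29,69.78,62.78,54.91,46.84,39.97,39.47,40.54,48.55,56.86,64.57,70.46,67.21,61.4,58.65,48.45,45.17,46.23,53.87,61.96,48.19,59.26,66.54,72.58,82.05,88.37,88.37,92.84,93.86,94.58,90.25,87.79,78.89,75.3,64.67,56.14,48.52,28.45,25.76,25.99,27.82,28.49,27.98,25.57,25.37,26.43,30.31,36.59,42.87,48.61,54.56,56.24,59.03,60.18,57.25,55.79,36.14,36.74,34.44,37.95,37.93,39.67,37.72,34.29,33.92,36.51,39.67,37.7,70.58,66.88,63.48,63.22,65.28,67.76,72.36,74.63,78.63,80.85,77.71,76.63,70.93,69.17,66.91,69.86,71.7,75.34,75.81,73.67
5,17.73,18.13,23.17,23.36,29.38,34.21,41.64,48.73,54.05,62.95,68.15,75.82,82.9,88.08,90.41,91.81,93.29,23.28,30.87,33.62,39.74,46.43,65.18,72.74,75.31,81.19,85.89,56.01,54.64,54.75,56.14,47.01,50.6,55.12,60.47,64.61,43.39,38.7,32,28.32,32.21,36.87,82.47,80.63,73.52,69.12,71.74,80.4,72.1,68.42,63.78,55.53,46.13,40.91,41.05,41.06,46.94,54.77,63.57,69.74,66.39,62.3,57.99,46.96,44.96,46.05,56.79,62.25,48.26,59.17,67.47,74.08,81.88,85.95,90.24,94.63,94.03,92.19,90.76,87.41,80.27,76.16,65.43,59.17,48.85,28.78,25.74,28.48,28.72,28.69,29.8,25.71,26.61,28.94,28,36.9,42.96,48.39,54.58,57.24,60.45,59.76,57.95,57.78,39.26,33.26,34.13,37.68,40.88,40.48,39.46,33.73,34.81,40.58,41.09,41.38,76.18,72.7,68.06,68.01,69.58,72.91,78.26,79.98,83.79,85.5,82.92,80.74,77.62,74.48,72.07,74.96,77.34,80.88,79.54,80.77
6,17.36,17.32,18.14,22.34,28.13,31.95,38.37,46.62,52.76,60.77,65,72.68,79.48,83.85,88.87,89.63,89.48,21.44,28.32,31.8,36.17,45.29,62.76,68.48,70.88,77.94,84.11,51.33,53.87,52.78,54.04,45.16,49.74,54.17,56.03,61.84,40.64,35.44,28.84,26.97,27,36.2,81.51,75.4,70.25,67.48,70.47,76.83,69.95,66.68,60.03,53.09,47.49,38.24,37.86,39.23,46.98,52.9,63.09,68.15,63.2,60.32,53.62,45.83,41.64,44.61,55.18,59.57,46.36,56.15,66.08,73,81.45,83.04,88.39,91.77,92.71,92.78,89.33,85.26,80.24,73.52,63.67,57.56,46.96,25.7,25.26,24.33,26.59,26.54,29.13,25.79,25.33,23.84,27.83,35.68,43.37,48.28,52.43,56.96,58.53,59.11,56.37,56.82,36.76,34.18,34.41,36.25,38.88,38.09,37.57,33.38,34.84,36.43,38.36,36.37,75.27,69.24,66.05,66.19,68.58,71.68,76.23,79.71,81.67,82.95,81.01,77.71,74.84,71.55,70.75,71.99,75.96,76.91,78.86,78.08
7,16.9,18.15,20.16,23.56,28.94,34,41.67,46.88,54.56,61.19,67.83,75.9,81.72,86.47,89.54,91.75,93.59,23.84,29.64,33.42,38.31,44.17,63.77,72.74,73.4,79.55,86.8,52.27,52.57,55.56,55,47.46,50.52,56.45,58.78,64.73,41.72,38.11,32.06,27.69,31.79,40.11,79.93,80.08,73.72,67.65,70.56,78.77,71.78,68.61,62.58,52.49,46.96,40.74,39.56,40.96,45.97,54.44,64.06,69.47,65.74,63.23,55.96,47.09,46.66,45.58,53.08,61.69,49.96,59.07,67.73,75.71,83.03,88.28,90.41,94.14,95.21,92.93,93.81,89.2,80.79,74.95,65.46,56.49,49.23,27.59,26.86,29.65,26.59,28.81,30.08,26.24,29.16,27.25,29.78,36.15,43.23,49.17,53.32,60.45,58.65,60.32,59.18,58.53,39.83,35.87,34.94,37.37,41.4,39.78,39.56,36.09,34.88,39.26,40,40.64,75.82,71.96,69.12,69.05,71.64,71.34,77.69,83.5,83.79,85.91,84.47,79.28,76.71,74.69,71.13,75.45,77.19,78.45,78.52,80.26
8,17.51,18.76,22.22,24.82,28.8,34.38,40.59,46.89,53.6,62.94,69.97,76.31,81.87,88.44,90.04,93.5,93.4,23.7,30.71,33.4,40.95,45.13,65.67,72.28,76.57,81.25,88.39,56.93,55.08,54.87,57.29,47.2,50.06,57.56,59.77,65.77,42.83,39.41,33.73,28.92,31.46,39.17,81.67,79.44,74.69,70.88,73.48,80.63,73.82,68.92,64.83,56.04,46.24,41.07,39.87,42.91,48.23,57.43,64.04,68.85,67.36,62.41,56.19,48.59,45.05,47.49,55.73,63.05,51.51,62.43,72.16,77.88,85.39,88.52,92.47,96.17,95.09,94.94,93.18,89.22,82.37,79.2,69.17,59.89,49.91,30.9,29.01,28,30.42,31.08,29.84,29.14,28.48,30.81,30.08,39.35,44.4,49.91,56.63,60.51,61.11,62.83,61.17,58.55,40.3,37.49,36.6,40.12,42.42,43.07,39.97,38.45,36.3,40.34,41.96,40.99,76.11,72.06,70.36,70.51,71.53,73.79,77.72,82.9,84.89,86.5,85.55,83.06,78.51,75.04,73.85,74.42,76.85,81.28,82.37,80.84
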