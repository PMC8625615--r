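"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,22.61,22.77,22.95,27.05,31.29,37.48,41.51,50.57,56.09,63.16,68.94,75.36,80.61,84.15,86.86,91.46,92.58,27.18,30.26,36.02,39.81,48.56,66.58,71.78,73.96,78.74,83.57,55.94,56.05,56.27,53.86,47.22,50.92,52.93,59.64,63.41,46.7,40.07,31.8,29.47,32.94,40.74,82.87,78.65,72.44,70.21,73.14,79.16,72.05,67.17,63.05,56.32,48.97,41.97,38.23,42.94,46.59,57.42,61.28,68.24,66.94,65.54,56.05,46.32,47.98,48.56,55.32,62.39,49.59,56.91,65.78,74.75,81.06,85.96,91,90.5,92.21,91.82,89.21,85.73,81.31,72.11,64.36,57.73,48.62,29.31,30.35,27.98,28.09,29.98,28.46,26.84,26.62,26.63,30.05,38.04,43.02,48.17,53.1,57.5,59.94,58.43,57.99,57.32,37.05,35.37,36.21,37.88,41.54,39.16,35.01,35.14,36.67,38.97,40.59,40.53,71.05,67.14,62.89,63.24,65.31,69.35,72.08,75.04,78.42,79.22,77.54,75,71.53,68.73,67.39,69.5,69.93,74.18,74.86,74.21
2,24.37,23.56,24.95,28.65,33.57,39.51,44.23,50.76,58.76,62.01,70.32,78.9,81.34,85.78,89.97,93.41,94.79,29.4,32.78,37.1,43.55,48.08,67.83,72.38,77.19,84.37,86.11,59.28,59.66,59.06,58.14,50.61,53.52,58.2,61.47,66.66,47.21,41.22,36.46,30.23,35.4,42.74,86.09,83.13,73.59,71.26,74.54,82.25,73.24,71.8,66.51,57.64,48.87,45.98,43.03,43.07,51.33,59.16,64.43,72.41,69.44,65.14,58.22,52.19,48.58,50.43,58.57,63.13,49.66,58.22,67.84,73.36,81.09,84.61,91.27,91.74,92.12,92.57,89.74,83.98,80.37,72.78,66,58.42,50.14,29.92,29.32,27.55,30.1,31.68,30.11,29.71,27.31,30.44,31.12,39.65,42.23,49.23,54.59,57.08,58.38,57.37,59.32,58.36,38.53,38.71,36.7,35.89,40.01,40.84,35.95,37.47,35.65,38.98,42.91,40.74,74.92,75.21,69.44,65.85,69.43,72.18,74.62,79.78,83.09,83.43,80.55,80.15,74.72,72.65,71.08,74.96,76.08,76.59,79.96,78.15
3,20.14,21.65,22.03,26.68,32.95,36.94,43.48,48.77,54.33,61.81,68.27,74.41,79.65,84.33,88.41,92.44,90.91,26.3,32.58,37.21,40.81,46.78,67.98,69.07,75.16,81.14,84.44,56.02,55.4,54.8,55.87,48.52,52.47,55.68,61.77,64.59,45.97,40.36,33.79,30.99,32.57,41.28,83.13,79.22,74.76,70.32,73.03,80.04,70.48,70.55,63.96,55.69,47.45,43.62,39.77,43.38,49.45,56.62,64.61,68.12,68.63,64.7,57.61,49.57,47.21,48.94,57.22,62.02,48.39,58.26,67.1,72.11,79.29,84.4,89.74,92.23,91.3,91.73,88.48,85.39,80.29,74.74,65.02,57.75,49.23,30.8,26.84,27.91,29.1,30.15,30.4,26.71,26.07,27.34,30.98,37.78,40.95,49.18,53.84,57.36,57.5,59.87,58.22,58.85,37.23,33.73,34.24,36.68,40.2,40.26,36.1,33.96,33.42,35.18,40.22,39.44,71.53,67.06,63.8,62.39,64.82,67.68,70.14,73.91,78.68,78.21,78.53,75.54,70.8,66.1,65.7,67.69,70.66,74.55,73.47,74.28
4,24.25,22.09,21.63,24.96,33.32,35.49,41.46,48.03,53.84,62.29,68.22,74.6,78.03,83.52,88.81,91.43,91.19,26.76,29.37,37.76,40.52,44.73,65.03,68.71,75.26,81.45,84.89,56.87,54.36,54.01,56.27,46.62,52.01,54.51,59.15,63.17,44.13,38.32,32.47,28.15,31.75,39.27,81.4,78.32,70.67,69.35,69.97,79.17,70.99,68.77,61.63,56.03,46.22,42.66,38.73,40.14,48.36,55.91,65.16,67.52,65.9,63.07,55.1,47.48,45.86,43.3,55.66,62.13,50.05,58.93,68.37,73.82,81.66,84.7,90.47,92.07,93.42,91.89,88.43,85.94,80.31,74.59,68.05,56.87,51.93,30.92,28.76,28.59,29.06,29.74,31.17,29.86,26.68,28.43,31.18,40.21,45.21,51.27,55.25,57.08,58.67,60.1,60.43,58.41,42.38,36.34,37.42,35.94,40.71,40.14,37.53,37.08,34.3,37.8,40.79,40.53,76.51,72.23,69.13,66.25,69.17,73.38,76.16,80.73,83.54,84.95,82.7,81.72,75.83,72.52,71.47,73.75,76.35,78.24,78.97,78.68
5,21.1,19.24,22.35,23.2,31.32,32,38.89,45.23,54.4,61.12,67.71,73.67,78.25,82.28,86.68,89.85,89.39,22.53,28.09,36.4,39.78,45.88,63.86,68.96,75.33,79.3,81.27,53.58,53,53.74,52.28,44.73,49.87,53.84,57.7,60.71,41.32,39.7,31.06,28.68,30.83,39.13,80.65,76.64,69.32,67.88,69.46,77.38,68.26,67.59,61.21,54.22,45.76,41.91,36.9,39.16,47.33,55.03,62.01,67.79,65.06,60.97,53.97,46.12,43.75,46.21,54.07,59.83,52.53,61.46,68.6,75.22,82.88,89.39,93.7,95.3,96.72,94.15,89.94,89.11,84.06,76.41,68.65,60.6,53.6,32.37,31.02,30.9,31.26,33.94,34.01,29.99,29.84,28.3,32.71,40.07,45.19,51.46,58.88,60.56,61.06,64.79,61.91,59.68,42.2,38.47,38.63,40.21,42.07,43.74,40.29,38.66,38.76,40.32,43.59,44.17,77.73,75.85,71.18,69.87,71.67,73.78,77.6,82.4,86.03,87.18,85.64,83.51,77.91,75,75.46,76.16,76.89,80.76,81.16,82.31
6,18.84,19.19,21.35,23.47,29.43,34.79,40.65,45.73,52.84,59.39,65.6,71.66,76.57,81.67,85.29,88.96,88.08,23.67,28.48,33.99,38.94,43.56,64.03,68.31,73.28,78.55,81.14,52.68,51.82,52.83,51.74,42.68,46.74,53.37,56.81,61.59,41.43,37.34,29.79,27.76,28.58,37.51,80.33,76.18,68.07,65.97,70.93,75.88,67.07,65.17,60.54,52.7,44.24,42.54,37.63,39.03,45.02,54.15,59.88,65.21,63.12,61.51,52.58,44.02,44.88,45.64,53.32,60.17,51.02,60.04,67.21,75.24,83.28,85.41,92.11,93.54,95.45,93.25,89.93,88.53,82.45,75.91,67.49,59.73,54.27,31.87,30.57,29.14,30.4,31.65,30.95,31.96,27.45,30.79,31.49,39.67,44.98,49.32,57.33,60.24,61.88,61.22,62.47,58.01,40.58,38.97,36.29,38.62,41.56,43.28,39.31,37.8,39.75,40.38,42.14,41.97,74.71,73.66,70.49,68.02,69.94,74.48,76.72,81.18,84.66,85.69,85.51,80.83,77.48,74.86,75.08,74.23,78.26,80,81.48,79.69
7,18.79,16.67,20.26,23.41,28.79,32.24,38.25,44.84,52.9,59.89,65.49,72.15,75.58,81.49,82.75,86.6,87.77,20.97,27.18,33.02,39.6,43.03,62.03,67.14,71.88,76.83,79.41,54.83,52.31,52.81,50.56,45.67,48.1,50.87,54.46,61.2,40.47,35.72,28.43,26.66,28.49,34.49,80.15,72.93,67.56,65.33,69.9,76.2,67.27,64.29,59.19,52.04,42.68,39.1,35.37,36.68,44.73,54.14,60.79,65.84,62.21,60.49,51.34,45.23,42.34,44.41,53.09,56.82,53.38,62.44,70.09,77.6,84.3,89.91,91.99,96.24,96.75,92.89,93.06,88.6,82.81,75.27,69.07,60.84,54.59,32.99,33.56,33.39,32.82,33.47,34.46,31.94,31.13,31.54,34.03,43.56,48.53,52.37,59.5,60.86,63.47,62.28,63.43,59.24,42.28,39.06,40.68,39.26,43.99,45.13,40.42,39.44,39.92,41.08,45.78,45.01,77.46,75.92,73.34,70.75,72.5,75.58,79.13,83.25,85.22,87.21,86.52,84.3,78.48,77.46,75.7,77.93,80.03,81.43,81.93,80.56
8,23.43,25.07,23.18,27.71,32.64,38.24,44.54,50.01,57.43,65.29,70,77.19,81.76,88.12,90.67,93.86,92.91,30.07,32.45,36.87,41.86,48.58,67.51,75.05,77.44,83.3,87.21,58.9,57.96,58.59,56.88,51.7,52.84,58.31,60.76,67.17,46.96,40.45,36.81,30.07,34.63,41.5,83.96,79.66,72.41,72.32,76.45,80.29,73.19,70.44,65.66,58.16,49.04,42.57,40.04,45.35,49.75,57.95,64.82,70.36,69.86,65.54,58.33,50.84,49.15,50.57,58.74,63.53,51.52,61.65,69.62,76.16,81.73,88.41,92.23,93.73,94.63,92.65,90.45,88.06,83.88,74.73,68.47,58.96,52.64,31.84,29.37,30.12,32.63,32.6,33.73,30.65,31.2,30.21,30.74,41.62,43.02,50.59,57.04,59.86,61.63,61.39,60.49,59.74,42.03,38.78,37.57,38.93,44.91,42.41,39.55,38.17,36.92,39.72,42.43,42.84,76.8,74.79,71.75,70.13,71.57,72.65,76.87,81.3,84.35,84.64,84.55,79.79,77.99,74.96,73.73,75.58,75.98,81.79,81.4,80.42
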