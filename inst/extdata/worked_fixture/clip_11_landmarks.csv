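"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,22.71,22.78,25.12,25.83,30.33,36.61,43.02,51.29,56.34,66.01,72.13,77.65,85,88.79,92.31,93.54,96.06,26.66,31.43,35.52,42.09,46.02,68.78,73.52,76.53,83.12,86.97,56.66,57.37,58.91,58.52,48.29,53.41,57.55,62.75,66.89,44.52,38.13,35.19,30.04,33.71,40.69,83.69,82.45,75.53,71.05,73.89,81.97,74.53,71.29,66.34,57.4,50.64,43.71,41.19,46.29,49.61,57.23,67.92,71.56,67.56,62.51,58.3,49.62,47.1,48.93,58.05,63.18,48.01,59.21,68.95,76.16,83.15,87.23,93.29,95.81,95.09,94.31,92.96,90.06,81.88,75.54,67.59,56.32,51.13,27.53,26.47,27.38,26.78,28.56,28.59,27.58,26.95,28.69,29.26,37.26,45.54,50.2,55.26,59.05,58.59,61.01,60.48,58.94,37.63,36.97,36.61,39.08,39.42,41.27,39.29,34.18,35.23,39.29,41.54,39.33,76.49,72.69,71.24,70.37,71.26,74.01,75.94,83.16,82.58,84.6,84.04,80.56,76.35,74.28,70.9,75.66,76.48,81.47,79.61,79.86
2,19,21.41,23.83,26.16,32.52,37.79,43.86,49.58,57.52,63.81,71.79,77.37,83.58,87.46,93.14,94.64,95.84,25.71,31.23,35.67,42.79,47.65,68.67,74.02,78.64,82.59,89.61,57.11,57.89,56.6,58.69,48.87,52.41,56.92,59.81,66.01,42.09,40.49,34.58,28.34,33.62,40.07,85.31,81.04,75.3,71.43,74.66,82.66,73.25,70.95,63.19,57.23,50.12,42.12,40.87,42.19,47.32,56.45,65.55,73.74,66.83,64.74,57.43,50,48.92,49.08,55.62,64.47,52.13,61.66,69.17,76.21,84.85,89.24,92.89,98.83,95.34,96.47,95.81,88.38,84.61,78.03,67.52,58.95,52.57,32.21,28.61,29.05,29.15,32.19,30.7,27.55,28.95,30.35,31.62,39.12,44.41,49.29,55.19,61.52,60.76,62.51,60.81,57.98,39.67,37.16,38.12,39.98,44.47,40.14,39.32,36.99,38.49,39.37,43.49,42.1,77.94,74.67,70.64,71.62,71.64,75.36,79.2,85.05,85.27,87.27,87.27,83.98,79.67,75.89,73.02,76.13,77.96,80.58,80.75,83.29
3,20.67,20.64,25.1,27.83,34.14,38.58,45.86,53.4,58.17,64.87,72.68,81.24,85.81,90.41,94.06,96.16,95.5,28.26,35.57,39.12,44.3,49.4,69.63,76.21,77.16,82.64,90.29,57.48,58.2,59.57,60.72,51.77,55.06,60.6,63.27,69.95,46.97,44.3,37.06,32.48,34.55,43.64,86.96,84.97,77.79,73.47,76.5,84.4,75.69,73.78,65.52,59.33,52.84,46.95,43.61,44.81,50.81,57.25,69.56,71.31,70.22,68.18,59.59,51.1,48.58,50.25,58.66,66.11,47.81,56.82,65.63,74.19,81.82,85.87,88.98,92.63,93.49,91.72,90.5,86.19,79.75,73.51,63.92,56.84,49.15,27.39,26.07,26,27.29,28.61,27.46,25.19,24.61,26.02,28.06,34.82,41.75,46.58,53.14,57.61,59.39,59.2,56.16,57.2,38.67,33.94,33.02,36.52,38.12,38.6,36.94,34.12,33.59,38.46,38.56,37.52,74.18,72.56,69.49,65.97,68.82,70.39,75.34,79.33,80.93,84.64,82.13,79.56,74.48,72.31,70.62,72.5,76.25,79.52,79.45,81.01
4,19.56,20.79,23.23,25.71,31.93,35.55,42.57,46.03,55.95,65.32,71.31,76.96,83.86,89.16,91.77,93.18,94.25,23.89,31.05,35.96,38.65,45.69,67.71,72.5,74.67,82.95,87.64,55.38,55.59,55.57,57.08,48.17,51.55,57.34,60.78,65,44.21,38.41,34.83,29.6,32.87,39.61,82.47,80.66,72.95,71.16,75.21,80.35,72.41,70.44,64.79,57.31,49.63,44.22,39.93,42.81,47.39,58.35,64.82,71.81,66.98,65.34,58.81,49.8,45.42,49.21,59.61,64.12,50.06,55.76,64.71,74.26,81.54,84.84,89.53,92.47,90.77,92.43,91.14,85.67,78.1,74.51,63.75,55.91,48.31,27.24,24.69,28.46,22.91,26.19,27.33,24.13,23.49,25.63,27.71,34.25,41.42,46.77,53.35,56.44,56.51,58.55,55.74,55.17,36.84,32.9,33.87,35.06,39.44,37.73,37.14,30.71,33.84,36.81,38.93,38.08,71.04,72.21,65.91,66.16,68.7,70.38,73.97,78.71,81.97,85.36,81.87,77.77,73.53,72.26,70.16,72.07,72.96,77.19,77.3,76.49
5,17.49,17.28,21.52,23.15,28.28,34.05,41.38,47.24,52.95,62.08,67.33,74.63,81.82,84.7,88.73,91.11,90.1,22.84,28.98,32.32,38.23,43.77,63.73,69.53,74.23,79.34,84.4,54.65,54.44,54.3,56.43,45.9,50.6,54.27,58.27,62.38,42.16,37.79,31.22,27.16,31.28,37.29,79.7,80.64,71.93,66.99,71.68,81.08,71.93,68.47,61.96,56.9,47.21,43.14,38.76,40.43,45.3,52.88,62.3,68.92,62.69,62.11,56.2,47.53,44.97,47.24,55.44,61.38,47.02,58.25,67.47,74.46,81.79,87.37,92.11,92.97,92.98,94.86,91.22,86.61,80.26,73.72,65.07,56.56,48.21,28.38,23.93,25.9,27.85,28.82,27.39,26.16,25.6,26.94,28.42,34.57,41.74,47.91,53.4,58.04,57.94,58.04,58.72,58.04,38.25,35.5,38.02,36.5,39.72,39.13,37.84,34.35,35,37.49,38.1,38.53,76.28,71.36,68.87,67.08,69.71,71.62,76.28,79.48,83.82,85.58,83.63,79.2,73.06,73.91,70.69,73.85,76.17,79.18,80.48,80.14
6,19.74,19.99,23.76,26.1,32.63,36.42,43.06,47.8,56.23,65.57,72.01,76.44,84.78,88,90.71,93.33,93.63,27.22,31.4,37.38,41.17,47.68,67.76,73.85,76.35,84.12,89.72,56.84,58.29,57.07,57.98,48.44,52.83,58.48,58.94,65.37,43.9,40.08,33.98,30.84,35.04,42.08,83.42,80.09,74.5,68.43,72.32,82.3,73.42,70.21,64.41,57.03,50,44.35,39.38,43.46,49.91,56.75,65.83,72.03,67.85,65.88,59.28,52.33,47.41,47.55,55.92,64.78,48.67,58.47,67.68,74.14,81.14,86.41,90.41,92.83,94.69,93.22,91.95,85.94,81.14,74.29,66.2,58.79,49.43,27.17,24.72,26.84,27.39,27.44,30.68,27.47,28.34,27.71,28.48,37.19,42.51,49.39,52.61,56.75,59.28,59.08,57.6,58.92,34.21,34.99,32.93,38.24,39.87,39.23,36.02,35.94,34.97,39.21,39.25,38.37,70.8,65.51,64.87,63.57,63.31,68.78,72.01,76.69,78.05,79.86,80.49,76.74,73.07,69.05,69.69,69.26,74.56,75.21,77.78,74.67
7,18.55,18.82,20.48,22.98,29.19,34.13,40.25,47.99,55.11,62.62,68.77,76,83.52,86.9,91.51,94.47,91.29,23.01,27.7,34.65,39.72,45.83,66.1,71.69,73.44,80.44,87.45,55.07,54.47,54.9,54.84,47.57,51.42,54.99,58.02,64.45,40.73,39.46,31.1,28.92,32.44,37.87,83.46,77.7,72.95,69.81,71.2,80.38,70.59,68.23,62.45,54.38,46.28,41.45,38,41.71,46.45,53.16,63.48,67.57,65.98,61.74,54.67,47.56,44.5,47.29,54.85,61.33,49.75,58.13,68.78,74.91,81.81,85.58,91.79,94.45,93.94,95.3,91.88,86.47,81.05,76.39,66.98,57.86,50.47,29.54,26.89,26.46,28.32,27.37,29.82,26.12,27.84,27.11,28.66,36.75,43.98,47.05,55.02,56.65,59.98,60.71,57.73,59.56,37.53,34.94,34.1,38.19,40.87,38.77,38.52,34.42,36.07,37.98,39.45,39.88,74.84,72.23,68.89,66.2,69.92,72.76,77.26,79.11,84.13,85.71,82.94,81.08,75.89,75.41,72.37,75.24,75.65,80.57,82.29,81.05
8,18.69,18.66,21.6,25.18,30.02,35.69,40.77,49.04,53.44,62.39,69.25,76.09,83.16,86.99,91.55,90.45,94.14,24.51,30.7,35.3,39.8,44.22,66.58,72.18,74.83,79.9,86.66,55.71,56.75,55.1,55.24,45.08,50.78,55.83,57.79,64.42,43.02,37.53,34.15,29.21,31.97,38.12,83.09,79.34,72.04,68.85,72.88,80.01,71.88,68.44,64.61,55.29,46.22,42.86,39.06,43.53,47.55,55.29,64.46,70.61,67.3,64.67,54.2,49.12,45.98,46.36,54.79,61.8,52.66,60.91,69.45,75.92,84.61,87.5,93.53,96.41,97.22,96.6,94.7,89.93,83.89,77.75,68.88,61.28,52.25,29.74,28.07,27.9,29.41,31.26,31.39,29.12,29.73,29.83,31.79,39.92,45.11,51.4,56.43,60.99,61.85,63.31,62.51,60.42,41.15,36.47,37.94,41.31,44.34,42.18,41.43,37.61,36.44,39.79,42.47,41.76,77.62,72.52,70.78,71.08,72.49,75.13,79.06,84.33,85.44,87.89,86.96,83.34,78.09,78.13,75.17,76.26,80.69,82.49,85.15,82.89
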