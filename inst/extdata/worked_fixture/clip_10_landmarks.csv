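"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,19.33,19.79,22.68,25.89,31.38,38.37,42.43,51.4,55.64,63.2,73.06,76.8,84.17,88.52,92.77,94.85,94.16,26.64,32.5,36.99,41.2,51.12,68.63,73.31,77.92,81.43,87.97,58.44,58.75,55.85,58.94,49.5,54.18,59.52,60.76,67.31,43.85,40.55,33.77,31.4,32.93,40.56,84.17,82.15,76.32,69.76,75.4,83.88,73.12,70.26,65.2,58.67,51.14,43.27,41.04,42.9,48.19,57.15,65.8,74.49,67.29,63.95,57.69,50.38,47.23,48.88,58.99,63.96,49.59,57.13,68.76,73.38,81.45,88.02,90.45,94.13,93.91,93.19,90.06,86.99,81.12,74.72,67.25,57.83,48.64,30.12,26.64,28.02,27.35,27.31,28.59,26.24,24.96,26.65,29.19,36.57,43.93,46.19,54.32,57.24,58.08,61.45,58.49,57.08,39.67,36.08,35.91,37.65,41.35,39.67,37,35.91,34.63,36.67,39.58,41.24,74.3,67.38,64.66,61.97,65.45,66.15,73.07,76.37,78.21,81.45,79.95,75.95,71.52,69.33,67.69,70.98,71.72,74.68,75.59,75.48
2,19.1,22.36,23.66,28.12,33.34,35.24,44.33,51.67,57.77,66.53,72.51,77.75,84.73,90.37,94.19,96.63,94.65,27.36,32.73,37.54,43.2,48.74,69.55,75.97,78.12,83.47,88.35,57.78,58.54,59.98,59.72,50.45,54.91,58.69,61.66,67.28,46.79,41.43,32.69,33.08,35.29,40.76,84.89,85.63,76.15,72.94,77.36,82.56,76.07,72.53,66.66,57.32,50.81,45.3,42.36,43.41,49.36,61.45,66.74,73.63,69.68,64.76,59.45,50.25,49.34,47.84,57.49,65.87,49.19,59.1,69.44,76.79,83.83,88.32,91.73,96.75,95.77,96.16,94.69,89.95,82.12,76.17,67.65,59.69,51.66,30.76,27.81,28.83,29.37,32.53,31.33,30.11,28.75,31.72,32.45,38.5,44.44,50.77,57.72,58.06,60.59,63.42,61.08,57.92,39.49,37.78,37.02,41.35,42.8,42.75,38.92,36.07,37.14,40.88,43.27,42.9,76,71.55,68.68,68.87,70.81,72.91,76.32,80.67,84.44,83.96,87.03,80.15,75.77,74.84,73.33,74.14,77.41,81.16,81.85,81.05
3,19.69,21.3,21.63,27.35,32.6,38.49,43.84,52.22,57.83,67.06,71.06,78,84.43,89.58,93.92,94.38,95.02,27.29,31.19,35.99,40.71,47.05,68.03,74.5,78.68,84.58,88.54,58.92,57.57,57.65,59.9,48.72,55.09,57.9,62.83,67.7,45.17,41.58,33.55,32.51,33.22,41.06,84.19,83.31,74,71.73,74.41,82.28,74.23,72.95,66.35,58.48,51.01,43.56,40.68,42.82,48.96,57.5,67.48,71.94,69.08,64.9,58.82,50.59,47.9,49.16,57.62,64.1,48.01,58.86,63.76,74.17,78.51,83.67,89.58,92.74,93.39,91.56,89.48,87.66,80.5,72.54,65.49,55.02,46.67,28.35,24.32,26.48,25.83,26.37,26.61,27.47,24.92,25.94,27.14,36.02,42.14,47.31,51.79,54.92,57.73,58.99,57.28,56.13,37.61,29.97,33.31,35.92,40.29,37.82,35.98,34.39,32.81,37.55,38.07,38.89,71.22,66.6,63.92,63.78,63.93,65.53,71.82,75.64,76.27,79.81,76.87,73.25,70.56,66.83,64.97,67.92,71.33,74.89,75.69,73.79
4,21.37,20.01,24.57,25.16,31.61,38.14,43.26,52.25,57.01,65.84,71.97,78.89,85.66,89.69,92.62,93.44,93.51,24.65,32.15,35.38,42.03,48.14,67.89,75.22,75.82,80.61,88.55,56.5,56.16,58.37,59.78,50.78,55.28,59.43,60.82,66.32,46.18,39.39,34.44,30.02,33.8,41.93,84.42,81.78,73.06,71.71,75.87,83.11,74.15,70.57,67.6,57.86,51.45,44.73,43.04,43.31,49.19,57.41,65.64,72.51,67.9,65.64,58.07,51.41,49.09,50.25,57.49,64.38,48.14,56.68,65.86,73.63,80.28,85.93,89.43,92.2,92.81,92.75,88.73,84.68,79.49,72.77,64.61,54.41,47.9,26.47,25.76,24.34,23.84,28.16,29.44,23.83,23.99,26.12,28.42,35.09,41.35,45.89,52.12,57.24,57.36,58.13,56.26,55.94,37.1,34.54,32.3,35.73,38.63,36.74,36.43,32.29,31.99,35,37.32,38.4,72.72,68.99,66.29,62.27,67.96,68.3,73.97,75.54,79.73,81.16,80.69,77.39,72.53,70.07,68.09,74.66,73.42,77.01,77.59,76.75
5,16.48,18.76,21.85,22.97,29.92,34.65,41.44,48.63,54.48,61.6,70.64,76.57,82.92,87.08,86.48,90.21,92.65,25.68,29.13,32.18,38.88,46.24,63.98,70.93,75.34,80.11,86.09,57.11,55.86,53.62,55.8,47.78,50.23,54.53,59.37,63.49,42.1,38.9,29.54,28.13,31.3,37.92,81.26,79.42,73.13,70.45,72.28,79.25,71.63,67.96,62.74,53.52,47.83,41.65,39.83,40.92,46.14,54.78,63.24,70.74,66.49,64.07,54.61,46.46,44.38,47.84,53.27,60.23,48.18,57.58,67.21,73.83,80.04,85.56,90.71,94.54,92.64,94.36,91.42,86.17,80.69,77.29,64.8,57.31,48.41,30.2,26.17,25.74,26.64,27.82,29.33,23.84,25.37,25.44,30.04,39.98,42.04,46.03,52.81,57.41,59.84,59.33,58.42,58.37,38.08,35.42,34.12,36.9,37.88,38.45,36.76,35.1,34.77,37.6,40.21,38.96,70.57,67.95,63.91,59.85,66.36,69.42,71.53,76.15,79.95,81.3,78.53,75.96,70.9,68.62,67.66,69.45,72.3,76.34,77,76.05
6,15.32,19.18,19.86,23.17,27.54,33.12,40.19,48.81,52.51,61.67,67.85,73.86,81.69,84.84,88.53,89.84,91.28,23.82,28.24,34.32,37.68,44.68,63.68,68.86,72.7,79.88,85.7,53.49,53.57,53.37,55.35,46.53,49.86,54.79,59.04,63.24,41.94,34.14,30.33,25.94,29.56,36.92,80.68,79.53,70.8,67.02,71.11,78.13,70.09,69.18,60.93,55.13,45.91,40.18,36.19,40.34,46.92,54.8,62.81,67.72,64.18,60.85,53.11,46.98,42.36,46.79,54.07,60.15,51.42,58.32,67.72,75.62,82.12,88.67,92.78,93.66,94.78,94.83,91.72,88.09,82.58,75.99,67.44,59.11,50.61,30.34,27.44,28.98,28.93,29.72,30.79,27.7,27.03,28.59,29.03,39.17,42.77,48.69,54.82,58.07,60.51,60.75,59.24,59.32,40.8,37.51,34.84,38.78,42.24,41.08,38.42,36.69,37.36,39.88,42.89,40.23,71.56,70.46,65.68,64.73,67.83,69.28,73.83,77.73,80.3,82.14,80.92,78.29,73.9,69.62,68.26,71.49,74.46,75.59,77.21,76.23
7,19.59,19.39,23.09,25.18,30.48,35.77,41.24,49.06,55.03,61.34,70.67,75.6,83.42,87.11,91.71,91.73,93.57,23.98,30.59,34.14,39.79,45.84,67.03,73.59,74.53,82.08,86.86,54.75,54.89,54.97,55.51,49.15,50.14,55.41,58.57,64.64,41.59,38.84,33.23,28.16,30.41,38.62,83.6,78.38,71.67,67.31,71.32,81.49,71.74,68.85,64.86,55.57,47.62,41.71,38.32,42.43,46.33,54.59,66.09,69.89,66.66,63.25,56.62,49.04,46.01,47.85,55.72,61.66,51.22,61.33,68.75,77.03,82.42,85.87,92.53,93.79,96.27,94.92,94.79,89.49,78.99,76.16,67.12,60.43,50.25,29.28,29.29,28.72,29.49,31.3,31.42,26.33,25.68,30.44,30.28,38.07,43.71,47.2,56.04,60.4,61.4,61.19,60.68,59.14,37.42,36.63,36.65,38.72,42.46,41.74,40.56,36.88,36.84,39.58,41.42,39.94,74.16,71.37,69.16,66.78,69.94,70.79,76.01,82.05,85.17,84.53,85.16,81.68,76.65,72.89,71.05,76.39,74.71,78.69,82.45,80.68
8,20.4,18.95,24.16,24.42,31.25,35.65,42.92,50.82,56.18,65,71.07,77.32,84.45,88.34,91.32,93.17,94.04,25.12,31.27,37.7,41.98,47.64,67.35,73.55,76.34,80.98,87.12,57.21,57.58,58.35,57.65,49.5,54.01,59.87,61.12,65.67,44.2,40.65,35.27,29.45,33.31,39.86,84.02,81.11,74.99,72.15,72.74,82.27,72.01,71.07,65.63,56.12,48.61,42.55,39.97,43.64,48.64,56.04,65.99,69.75,67.01,63.2,56.61,50.37,45.97,47.82,56.1,64.11,53.05,61.44,71.46,79.42,85.79,90.02,95.14,96.65,97.67,95.2,93.96,90.25,84.06,76.54,69.13,59.93,51,32.02,29.16,30.84,30.51,30.43,32.56,29.91,29.76,29.92,31.07,38.6,46.38,51.18,57.39,60.08,60.6,63.48,61.07,60.33,39.94,39.18,38.78,41.55,40.48,42.08,40.26,38.3,37.21,41.12,41.35,40.03,75.43,70.09,66.4,66.19,69.06,71.14,74.64,79.62,81.87,83.23,82.63,79.83,75.92,70.79,71.05,74.25,73.64,79.05,79.7,79.9
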